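#' Residue hydropathy scales
#'
#' Loads a per-residue hydropathy scale as a `hydropathy_scale` object. Two
#' scales ship with the package:
#'
#' * `"kd"` — the Kyte–Doolittle hydropathy index (dimensionless; larger =
#'   more hydrophobic).
#' * `"biological"` — the translocon-based "biological" hydrophobicity scale:
#'   the apparent free energy of membrane insertion, Delta-G-app, in kcal/mol
#'   (published orientation: *smaller* = more hydrophobic). The scale is
#'   exposed negated so that, like Kyte–Doolittle, larger values mean more
#'   hydrophobic; the published raw values are retained in `$raw`.
#'
#' A custom scale can be supplied as a two-column table (`residue`, `value`)
#' via `source`, together with an explicit `orientation`. Orientation is
#' always declared, never inferred from the values.
#'
#' @param name Scale identifier. `"kd"` (alias `"kyte-doolittle"`) or
#'   `"biological"` for the packaged scales, or any label for a custom scale.
#' @param source Optional data frame with columns `residue` and `value`
#'   (one row per standard amino acid), or path to a TSV file with those
#'   columns. Required for custom scales.
#' @param orientation For custom scales: `"hydrophobic_positive"` if larger
#'   values mean more hydrophobic, `"hydrophobic_negative"` otherwise (the
#'   exposed values are then negated so that the working orientation is
#'   always larger-is-more-hydrophobic).
#' @return An object of class `hydropathy_scale`: a list with `name`,
#'   `values` (named numeric vector over the 20 standard residues, oriented
#'   larger = more hydrophobic), `raw` (the values as published/supplied),
#'   `orientation` (orientation of `raw`), and `units`.
#' @examples
#' kd <- load_scale("kd")
#' kd$values[c("I", "R")]
#' bio <- load_scale("biological")
#' bio$values["I"] > bio$values["D"]
#' @export
load_scale <- function(name, source = NULL, orientation = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- tolower(name)
  units <- "dimensionless"
  if (is.null(source)) {
    if (key %in% c("kd", "kyte-doolittle", "kyte_doolittle")) {
      source <- system.file("extdata", "scales", "kyte_doolittle.tsv",
                            package = "loopchap", mustWork = TRUE)
      orientation <- "hydrophobic_positive"
      name <- "kd"
    } else if (key == "biological") {
      source <- system.file("extdata", "scales", "biological_dgapp.tsv",
                            package = "loopchap", mustWork = TRUE)
      orientation <- "hydrophobic_negative"  # published Delta-G-app
      units <- "kcal/mol (apparent insertion free energy)"
      name <- "biological"
    } else {
      stop("unknown built-in scale '", name,
           "'; supply `source` for a custom scale", call. = FALSE)
    }
  }
  if (is.character(source)) {
    source <- utils::read.delim(source, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(source),
            all(c("residue", "value") %in% names(source)))
  if (is.null(orientation)) {
    stop("orientation must be declared for a custom scale", call. = FALSE)
  }
  orientation <- match.arg(orientation,
                           c("hydrophobic_positive", "hydrophobic_negative"))
  res <- toupper(as.character(source$residue))
  if (anyDuplicated(res)) {
    stop("duplicate residue entries: ",
         paste(unique(res[duplicated(res)]), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(AA_STANDARD, res)
  if (length(missing)) {
    stop("scale is missing residue entries: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw <- stats::setNames(as.numeric(source$value), res)[AA_STANDARD]
  if (any(!is.finite(raw))) stop("non-finite scale values", call. = FALSE)
  values <- if (orientation == "hydrophobic_negative") -raw else raw
  structure(
    list(name = name, values = values, raw = raw,
         orientation = orientation, units = units),
    class = "hydropathy_scale"
  )
}

#' @export
print.hydropathy_scale <- function(x, ...) {
  cat("Hydropathy scale:", x$name, "(", x$units, ")\n")
  cat("Published orientation:",
      if (x$orientation == "hydrophobic_positive")
        "larger = more hydrophobic" else "smaller = more hydrophobic",
      "(exposed values always larger = more hydrophobic)\n")
  print(round(x$values, 3))
  invisible(x)
}

# the 20 standard one-letter codes
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# sum of oriented scale values over a residue string ("" -> 0)
.residue_sum <- function(seq, scale) {
  stopifnot(inherits(scale, "hydropathy_scale"))
  if (is.na(seq) || !nzchar(seq)) return(0)
  res <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(res, AA_STANDARD)
  if (length(bad)) {
    stop("invalid residue code(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  sum(scale$values[res])
}

#' Construct a loop-motif set
#'
#' A motif set describes the three short hydrophobic tripeptide motifs in a
#' chaperone-domain loop, plus the anchor residue at position 206 (Thr in the
#' wild type, Trp in the T206W reporter mutant). Deletion (delta-loop)
#' variants are represented by empty motifs.
#'
#' @param variant_id Variant identifier.
#' @param motif1,motif2,motif3 Amino-acid strings (typically length 3; `""`
#'   for deletion variants).
#' @param anchor206 Single residue (or `""` if absent).
#' @return An object of class `motif_set`.
#' @examples
#' motif_set("wt-like", "FII", "LIV", "VFA", "T")
#' motif_set("delta-loop", "", "", "", "T")
#' @export
motif_set <- function(variant_id, motif1 = "", motif2 = "", motif3 = "",
                      anchor206 = "") {
  stopifnot(is.character(variant_id), length(variant_id) == 1L,
            nzchar(variant_id))
  parts <- c(motif1 = motif1, motif2 = motif2, motif3 = motif3,
             anchor206 = anchor206)
  parts[is.na(parts)] <- ""
  for (p in parts) {
    if (nzchar(p)) {
      bad <- setdiff(strsplit(toupper(p), "")[[1]], AA_STANDARD)
      if (length(bad)) {
        stop("invalid residue code(s) in motif: ",
             paste(unique(bad), collapse = ", "), call. = FALSE)
      }
    }
  }
  if (nchar(parts[["anchor206"]]) > 1L) {
    stop("anchor206 must be a single residue or empty", call. = FALSE)
  }
  structure(as.list(c(variant_id = variant_id, parts)), class = "motif_set")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("Motif set '%s': [%s] [%s] [%s] + anchor206 '%s'\n",
              x$variant_id, x$motif1, x$motif2, x$motif3, x$anchor206))
  invisible(x)
}

#' Combined hydropathy of a motif set
#'
#' Sums per-residue scale values over motifs 1–3 plus the position-206 anchor
#' residue, on the scale's working orientation (larger = more hydrophobic).
#' The combined score is the x-axis of the hydropathy–activity regression.
#'
#' @param motifs A [motif_set()].
#' @param scale A [load_scale()] object.
#' @return A one-row data frame with `variant_id`, `scale_name`, per-motif
#'   partial sums (`motif1`, `motif2`, `motif3`, `anchor206`) and `combined`.
#' @examples
#' kd <- load_scale("kd")
#' motif_hydropathy(motif_set("egr", "EGR"), kd)$combined  # -8.4
#' @export
motif_hydropathy <- function(motifs, scale) {
  stopifnot(inherits(motifs, "motif_set"))
  per <- vapply(c("motif1", "motif2", "motif3", "anchor206"),
                function(f) .residue_sum(motifs[[f]], scale), numeric(1))
  data.frame(variant_id = motifs$variant_id, scale_name = scale$name,
             motif1 = per[["motif1"]], motif2 = per[["motif2"]],
             motif3 = per[["motif3"]], anchor206 = per[["anchor206"]],
             combined = sum(per), stringsAsFactors = FALSE)
}

#' Score a panel of motif sets
#'
#' Vectorizes [motif_hydropathy()] over a panel of variants, preserving the
#' input order.
#'
#' @param panel A list of [motif_set()] objects, or a data frame with columns
#'   `variant_id`, `motif1`, `motif2`, `motif3`, `anchor206` (as read by
#'   [read_motif_table()]).
#' @param scale A [load_scale()] object.
#' @return A data frame with one row per variant (same columns as
#'   [motif_hydropathy()]).
#' @export
score_panel <- function(panel, scale) {
  if (is.data.frame(panel)) {
    need <- c("variant_id", "motif1", "motif2", "motif3", "anchor206")
    miss <- setdiff(need, names(panel))
    if (length(miss)) {
      stop("motif table is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    panel <- lapply(seq_len(nrow(panel)), function(i) {
      motif_set(panel$variant_id[i], panel$motif1[i], panel$motif2[i],
                panel$motif3[i], panel$anchor206[i])
    })
  }
  ids <- vapply(panel, `[[`, character(1), "variant_id")
  if (anyDuplicated(ids)) {
    stop("duplicate variant_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(panel, motif_hydropathy, scale = scale))
  rownames(out) <- NULL
  out
}

#' Read a motif table
#'
#' Reads a TSV with columns `variant_id`, `motif1`, `motif2`, `motif3`,
#' `anchor206`. Empty cells denote deleted motifs.
#'
#' @param path Path to the TSV file.
#' @return A data frame suitable for [score_panel()].
#' @export
read_motif_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", na.strings = NULL)
  need <- c("variant_id", "motif1", "motif2", "motif3", "anchor206")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("motif table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tab
}
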