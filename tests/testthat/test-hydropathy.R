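test_that("built-in scales load complete, correctly oriented tables", {
  kd <- load_scale("kd")
  expect_s3_class(kd, "hydropathy_scale")
  expect_setequal(names(kd$values), strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]])
  # published Kyte-Doolittle entries (table lookup oracle)
  expect_equal(unname(kd$values["I"]), 4.5)
  expect_equal(unname(kd$values["R"]), -4.5)
  expect_gt(kd$values["I"], kd$values["R"])

  bio <- load_scale("biological")
  # exposed values are the negated published Delta-G-app, so the residue
  # ordering by hydrophobicity must match the published ordering reversed
  expect_equal(unname(bio$values), unname(-bio$raw))
  expect_equal(order(bio$values), rev(order(bio$raw)))
  expect_gt(bio$values["I"], bio$values["D"])  # Ile inserts, Asp does not
})

test_that("incomplete or malformed scale tables are rejected", {
  kd_tab <- utils::read.delim(
    system.file("extdata", "scales", "kyte_doolittle.tsv",
                package = "loopchap"))
  expect_error(
    load_scale("custom", kd_tab[kd_tab$residue != "W", ],
               orientation = "hydrophobic_positive"),
    "missing residue.*W")
  expect_error(
    load_scale("custom", rbind(kd_tab, kd_tab[1L, ]),
               orientation = "hydrophobic_positive"),
    "duplicate")
  expect_error(load_scale("custom", kd_tab), "orientation")
  expect_error(load_scale("no-such-scale"), "unknown built-in")
})

test_that("motif scores are per-residue sums with an anchor contribution", {
  kd <- load_scale("kd")
  bio <- load_scale("biological")

  # hand-summed oracle: E(-3.5) + G(-0.4) + R(-4.5)
  expect_equal(motif_hydropathy(motif_set("egr", "EGR"), kd)$combined, -8.4)
  # empty motif set scores zero on any scale
  for (sc in list(kd, bio)) {
    expect_equal(motif_hydropathy(motif_set("dl"), sc)$combined, 0)
  }
  # anchor swap changes the score by exactly scale(W) - scale(T)
  wt <- motif_hydropathy(motif_set("wt", "FII", "LIV", "VFA", "T"), bio)
  tw <- motif_hydropathy(motif_set("tw", "FII", "LIV", "VFA", "W"), bio)
  expect_equal(tw$combined - wt$combined,
               unname(bio$values["W"] - bio$values["T"]))
  # combined equals the sum of the per-motif partial sums
  expect_equal(wt$combined,
               wt$motif1 + wt$motif2 + wt$motif3 + wt$anchor206)
  expect_error(motif_hydropathy(motif_set("bad", "FXI"), kd), "invalid")
})

test_that("additivity and hydrophobicity monotonicity hold on both scales", {
  set.seed(11)
  for (sc in list(load_scale("kd"), load_scale("biological"))) {
    expect_gt(motif_hydropathy(motif_set("i", "III"), sc)$combined,
              motif_hydropathy(motif_set("d", "DDD"), sc)$combined)
    for (rep in 1:20) {
      m <- paste(sample(names(sc$values), 3, replace = TRUE), collapse = "")
      split3 <- motif_hydropathy(motif_set("s", m), sc)$combined
      joined <- motif_hydropathy(
        motif_set("j", substr(m, 1, 1), substr(m, 2, 2), substr(m, 3, 3)),
        sc)$combined
      expect_equal(split3, joined)
      # mutating residue 1 to a strictly more hydrophobic one never
      # decreases the combined score
      better <- names(which.max(sc$values))
      mutated <- paste0(better, substr(m, 2, 3))
      expect_gte(motif_hydropathy(motif_set("m", mutated), sc)$combined,
                 split3)
    }
  }
})

test_that("score_panel is order-equivariant and rejects duplicate ids", {
  kd <- load_scale("kd")
  panel <- list(motif_set("wt", "FII", "LIV", "VFA", "T"),
                motif_set("egr", "EGR", "EGR", "EGR", "T"),
                motif_set("dl", "", "", "", "T"))
  tab <- score_panel(panel, kd)
  expect_equal(tab$variant_id, c("wt", "egr", "dl"))
  expect_equal(score_panel(panel[1], kd),
               motif_hydropathy(panel[[1]], kd))
  # delta-loop variant scores the anchor alone
  expect_equal(tab$combined[3], unname(kd$values["T"]))
  shuffled <- score_panel(panel[c(3, 1, 2)], kd)
  expect_equal(shuffled[order(shuffled$variant_id), ],
               tab[order(tab$variant_id), ], ignore_attr = TRUE)
  expect_error(score_panel(c(panel, panel[1]), kd), "duplicate")
})

test_that("motif tables round-trip through the TSV reader", {
  tab <- data.frame(variant_id = c("wt", "dl"),
                    motif1 = c("FII", ""), motif2 = c("LIV", ""),
                    motif3 = c("VFA", ""), anchor206 = c("T", "T"))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_motif_table(path)
  expect_equal(back, tab, ignore_attr = TRUE)
  scored <- score_panel(back, load_scale("kd"))
  expect_equal(scored$combined[2], unname(load_scale("kd")$values["T"]))
})
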