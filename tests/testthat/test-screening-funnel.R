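eight_feature_hypothesis <- function(radius = 1) {
  # the reference hypothesis shape: 3 acceptors, 2 donors, 2 hydrophobes,
  # 1 negative center
  pharmacophore(kind = c("HA", "HA", "HA", "HD", "HD", "HY", "HY", "NC"),
                x = c(0, 2, 4, 1, 3, 0, 4, 2),
                y = c(0, 1, 0, -1, -1, 2, 2, 3),
                z = 0, radius = radius)
}

test_that("pharmacophore scoring follows the declared formula", {
  hyp <- eight_feature_hypothesis()
  # features exactly on all centers: full score
  exact <- as.data.frame(hyp[, c("kind", "x", "y", "z")])
  res <- match_qfit(exact, hyp)
  expect_equal(res$qfit, 100)
  expect_equal(res$matched_features, 8)

  # no kind overlap: zero
  none <- data.frame(kind = "HY", x = 100, y = 0, z = 0)
  expect_equal(match_qfit(none, hyp)$qfit, 0)

  # hand-evaluated partial match: 2-feature hypothesis, one matched at
  # deviation exactly one radius
  hyp2 <- pharmacophore(c("HA", "HD"), x = c(0, 5), y = 0, z = 0, radius = 1)
  feats <- data.frame(kind = c("HA"), x = 1, y = 0, z = 0)
  got <- match_qfit(feats, hyp2)
  expect_equal(got$qfit, 100 * (1 / 2) * exp(-1), tolerance = 1e-12)

  # greedy one-to-one: a single molecule point cannot satisfy two features
  hyp3 <- pharmacophore(c("HA", "HA"), x = c(0, 0.5), y = 0, z = 0, radius = 1)
  one <- data.frame(kind = "HA", x = 0.1, y = 0, z = 0)
  expect_equal(match_qfit(one, hyp3)$matched_features, 1)

  # round-trip hypothesis JSON
  tmp <- tempfile(fileext = ".json")
  write_pharmacophore(hyp, tmp)
  expect_equal(as.data.frame(read_pharmacophore(tmp)), as.data.frame(hyp))
})

test_that("conformer feature typing finds donors, acceptors, rings, anions", {
  feb <- embed_conformer("CC(C)COc1ccc(cc1C#N)c1nc(c(s1)C(=O)O)C", seed = 7,
                         compound_id = "febuxostat")
  ft <- conformer_features(feb)
  expect_true(all(c("HA", "HD", "HY", "NC") %in% ft$kind))
  # the single carboxylic OH is the one donor
  expect_equal(sum(ft$kind == "HD"), 1)
  # one all-carbon ring (benzene); the thiazole is excluded
  expect_equal(sum(ft$kind == "HY"), 1)
  # carboxyl group contributes the negative center
  expect_gte(sum(ft$kind == "NC"), 1)
  # a matched score against its own features is perfect
  hyp <- pharmacophore(ft$kind[1:4], ft$x[1:4], ft$y[1:4], ft$z[1:4],
                       radius = 1)
  expect_equal(match_qfit(feb, hyp)$qfit, 100)
})

test_that("enrichment follows the closed formulas and identities", {
  # back-solved consistent counts for the reference decoy screen
  e <- enrichment(35, 52, 35, 6269)
  expect_equal(e$ef, 120.56, tolerance = 0.005)
  expect_equal(e$gh, 0.75, tolerance = 0.005)

  # perfect retrieval: EF = D/A, GH = 1
  p <- enrichment(35, 35, 35, 6269)
  expect_equal(p$ef, 6269 / 35)
  expect_equal(p$gh, 1)

  # empty or hitless screens
  expect_warning(z <- enrichment(0, 0, 35, 6269), "empty")
  expect_equal(c(z$ef, z$gh), c(0, 0))
  e0 <- enrichment(0, 10, 35, 6269)
  expect_equal(e0$ef, 0)
  expect_equal(e0$gh, 0)

  expect_error(enrichment(5, 3, 10, 100), "invariants")
  expect_error(enrichment(1, 40, 20, 50), "invariants")
  expect_error(enrichment(-1, 3, 10, 100), "non-negative")

  # property grid: GH in [0,1] and EF * (A/D) = precision
  grid <- expand.grid(Ha = c(0, 1, 5, 10), Ht = c(1, 5, 10, 40),
                      A = c(10, 20), D = c(50, 400))
  grid <- grid[grid$Ha <= grid$Ht & grid$Ha <= grid$A & grid$Ht <= grid$D &
                 (grid$Ht - grid$Ha) <= (grid$D - grid$A), ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    r <- enrichment(g$Ha, g$Ht, g$A, g$D)
    expect_gte(r$gh, 0); expect_lte(r$gh, 1)
    expect_equal(r$ef * g$A / g$D, g$Ha / g$Ht, tolerance = 1e-12)
  }
})

test_that("computed descriptors match the reference ADME table", {
  d <- basic_descriptors("CC(C)COc1ccc(cc1C#N)c1nc(c(s1)C(=O)O)C")
  expect_equal(round(d$mw, 2), 316.37)
  expect_equal(d$rotatable_bonds, 5)
  expect_equal(round(d$fraction_csp3, 2), 0.31)
  expect_equal(round(d$tpsa, 1), 111.5, tolerance = 0.11)
  expect_equal(lipinski_violations(d), 0L)

  simple <- basic_descriptors(c("C", "CCO"))
  expect_equal(simple$fraction_csp3, c(1, 1))
  expect_equal(simple$rotatable_bonds, c(0, 0))
  expect_equal(simple$mw[2], 46.07, tolerance = 0.01)

  heavy <- data.frame(mw = 600, logp = 6, hbd = 6, hba = 11)
  expect_equal(lipinski_violations(heavy), 4L)
})

test_that("the staged funnel reproduces the reference screen outcomes", {
  prof <- load_adme_profiles()
  prof$qfit <- 60  # matching scores are not printed; all six passed stage 1

  res <- run_funnel(prof)
  expect_equal(unname(res$counts["input"]), 6)
  # febuxostat's docking score (8.22) is below the stage-2 bar
  expect_false("Febuxostat" %in% res$stages$docking$compound_id)
  # all four screened hits survive every stage, 44 passes alongside them
  expect_setequal(res$stages$adme$compound_id,
                  c("VS12", "VS16", "VS19", "VS26", "44"))

  # the CYP rule (at most one inhibition flag) rejects febuxostat's
  # 3-flag profile at the ADME gate
  expect_false(adme_gate(prof[prof$compound_id == "Febuxostat", ]))
  cyp_flags <- prof[prof$compound_id == "Febuxostat",
                    c("cyp1a2", "cyp2c19", "cyp2c9", "cyp2d6", "cyp3a4")]
  expect_equal(sum(cyp_flags == "Yes"), 3)

  # strict printed bounds reject the hit with TPSA 130.3
  strict <- run_funnel(prof, funnel_config(precision_tol = FALSE))
  expect_false("VS26" %in% strict$stages$adme$compound_id)
  expect_true("VS12" %in% strict$stages$adme$compound_id)
})

test_that("funnel behaviour: order invariance, subsets, monotonicity,
           missing data", {
  set.seed(77)
  n <- 100
  cand <- data.frame(
    compound_id = sprintf("c%03d", 1:n),
    qfit = runif(n, 0, 100),
    docking_score = runif(n, 5, 13),
    mw = runif(n, 100, 600), tpsa = runif(n, 10, 150),
    gi_absorption = sample(c("High", "Low"), n, TRUE),
    bbb_permeant = sample(c("Yes", "No"), n, TRUE),
    sa_score = runif(n, 2, 6),
    lipinski_violations = sample(0:2, n, TRUE),
    cyp1a2 = sample(c("Yes", "No"), n, TRUE),
    cyp2c19 = sample(c("Yes", "No"), n, TRUE),
    cyp2c9 = sample(c("Yes", "No"), n, TRUE),
    cyp2d6 = sample(c("Yes", "No"), n, TRUE),
    cyp3a4 = sample(c("Yes", "No"), n, TRUE),
    stringsAsFactors = FALSE)
  cfg <- funnel_config()
  res <- run_funnel(cand, cfg)

  # independent row-by-row predicate oracle
  yes <- function(v) v == "Yes"
  keep <- cand$qfit > 35 & cand$docking_score > 10 &
    cand$mw > 149.5 & cand$mw < 500.5 &
    cand$tpsa > 19.5 & cand$tpsa < 130.5 &
    cand$gi_absorption == "High" & !yes(cand$bbb_permeant) &
    cand$sa_score < 4.55 & cand$lipinski_violations == 0 &
    (yes(cand$cyp1a2) + yes(cand$cyp2c19) + yes(cand$cyp2c9) +
       yes(cand$cyp2d6) + yes(cand$cyp3a4)) <= 1
  expect_setequal(res$stages$adme$compound_id, cand$compound_id[keep])

  # row order invariance and subset property
  perm <- sample(n)
  res_p <- run_funnel(cand[perm, ], cfg)
  expect_setequal(res_p$stages$adme$compound_id, res$stages$adme$compound_id)
  expect_true(all(res$stages$adme$compound_id %in% cand$compound_id))
  expect_true(all(res$stages$docking$compound_id %in%
                    res$stages$pharmacophore$compound_id))

  # tightening any bound never adds survivors
  tight <- run_funnel(cand, funnel_config(qfit_min = 60, dock_min = 11,
                                          tpsa_range = c(40, 100)))
  expect_true(all(tight$stages$adme$compound_id %in%
                    res$stages$adme$compound_id))

  # empty input and missing columns
  empty <- run_funnel(cand[0, ], cfg)
  expect_equal(unname(empty$counts), c(0, 0, 0, 0))
  nodock <- cand[, setdiff(names(cand), "docking_score")]
  res_nd <- run_funnel(nodock, cfg)
  expect_equal(unname(res_nd$counts["docking"]), 0)
  expect_true(any(grepl("missing column", res_nd$rejected$reason)))
  # a row with one missing ADME value is rejected with a reason
  cand2 <- cand; cand2$sa_score[1] <- NA
  res2 <- run_funnel(cand2, cfg)
  expect_true(!cand2$compound_id[1] %in% res2$stages$adme$compound_id ||
                !keep[1])
})
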