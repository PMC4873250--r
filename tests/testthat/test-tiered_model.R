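# The two-tier prediction schema: gate, one-vs-rest family stack, family
# resolution, and bundle persistence.

test_that("tier-1 gate learns well-separated synthetic classes", {
  gH <- make_family_generator("hsp", residue_bias = c(D = 5, E = 5),
                              length_range = c(40L, 80L))
  gN <- make_family_generator("bg", length_range = c(40L, 80L))
  hsp <- sample_records(gH, 50, seed = 1)
  bg <- sample_records(gN, 50, seed = 2)
  model <- build_tier1(hsp, bg, "coupled", kernel_config("rbf", gamma = 0.01))
  expect_identical(model$positive, "HSP")
  expect_equal(model$n_pos, 50); expect_equal(model$n_neg, 50)
  feats <- encode_dataset(.rbind_sets(hsp, bg), "coupled")$features
  labels <- rep(c(1, -1), each = 50)
  expect_gte(mean(predict_label(model, feats) == labels), 0.95)
  expect_error(build_tier1(hsp, hsp[0, ], "coupled"))
})

test_that("mixed-eligibility records are rejected in aggregate", {
  hsp <- protein_set(c("ok1", "tiny"), c("ACDEFACDEF", "A"))
  bg <- protein_set("n1", "MKVLWMKVLW")
  expect_error(build_tier1(hsp, bg, "coupled"), "tiny")
})

test_that("one-vs-rest builder yields one model per family", {
  marker <- setNames(c("A", "C", "D", "E", "F", "G"), hsp_families())
  gens <- lapply(setNames(nm = hsp_families()), function(f) {
    make_family_generator(f, residue_bias = setNames(5, marker[[f]]),
                          length_range = c(30L, 60L))
  })
  # realistically lopsided family sizes, scaled far down
  counts <- c(HSP20 = 7, HSP40 = 26, HSP60 = 4, HSP70 = 6, HSP90 = 3,
              HSP100 = 3)
  fam_records <- lapply(setNames(nm = hsp_families()), function(f) {
    sample_records(gens[[f]], counts[[f]], seed = match(f, hsp_families()))
  })
  models <- build_tier2(fam_records, "discrete", kernel_config("linear"))
  expect_length(models, 6L)
  expect_identical(names(models), hsp_families())
  for (f in hsp_families()) expect_identical(models[[f]]$positive, f)
  expect_error(build_tier2(fam_records["HSP20"], "discrete"), "2 families")
})

test_that("a family model recovers generator hold-outs", {
  gA <- make_family_generator("famA", residue_bias = c(D = 5, E = 5),
                              length_range = c(40L, 80L))
  gB <- make_family_generator("famB", residue_bias = c(K = 5, R = 5),
                              length_range = c(40L, 80L))
  models <- build_tier2(list(A = sample_records(gA, 30, seed = 1),
                             B = sample_records(gB, 30, seed = 2)),
                        "coupled", kernel_config("rbf", gamma = 0.01))
  holdA <- encode_dataset(sample_records(gA, 30, seed = 91), "coupled")$features
  expect_gte(mean(predict_label(models$A, holdA) == 1), 0.9)
})

test_that("verdicts respect the gate and resolve families by argmax", {
  pred <- toy_predictor()
  probes <- toy_probe_records(60)
  v <- predict(pred, probes)
  expect_equal(nrow(v), 60L)
  expect_identical(v$id, probes$id)
  # gate exclusivity: non-HSPs never carry a family or family scores
  non <- v[!v$is_hsp & is.na(v$error), ]
  expect_true(all(is.na(non$family)))
  expect_true(all(is.na(non$score.HSP20)))
  # resolution totality: every HSP verdict names exactly one family
  hs <- v[v$is_hsp & is.na(v$error), ]
  expect_true(all(hs$family %in% names(pred$tier2)))
  # family is the argmax of the reported scores
  for (k in seq_len(nrow(hs))) {
    sc <- unlist(hs[k, c("score.HSP20", "score.HSP70")])
    expect_identical(hs$family[k],
                     names(pred$tier2)[which.max(sc)])
  }
  # low-confidence flag iff the winning score is negative
  expect_identical(hs$confidence,
                   ifelse(pmax(hs$score.HSP20, hs$score.HSP70) >= 0,
                          "normal", "low"))
})

test_that("family score ties break by canonical order", {
  pred <- toy_predictor()
  # same model under two family names forces an exact tie everywhere
  tied <- tiered_predictor(pred$tier1,
                           list(HSP20 = pred$tier2$HSP70,
                                HSP70 = pred$tier2$HSP70))
  probes <- toy_probe_records(30)
  v <- predict(tied, probes)
  hs <- v[v$is_hsp & is.na(v$error), ]
  expect_true(nrow(hs) > 0)
  expect_true(all(hs$family == "HSP20"))
})

test_that("ineligible records yield error rows without stopping the run", {
  pred <- toy_predictor()
  probes <- .rbind_sets(toy_probe_records(5),
                        protein_set("stub", "A"))
  v <- predict(pred, probes)
  expect_equal(nrow(v), 6L)
  expect_identical(v$confidence[6], "error")
  expect_match(v$error[6], "too short")
  expect_true(all(is.na(v$error[1:5])))
})

test_that("all seven models must share one encoding", {
  pred <- toy_predictor()
  other <- toy_predictor(encoding = "discrete")
  expect_error(tiered_predictor(pred$tier1, other$tier2), "encoding")
})

test_that("bundle save/load round-trips verdicts and decision values", {
  pred <- toy_predictor()
  probes <- toy_probe_records(100)
  dir <- tempfile("bundle")
  save_bundle(pred, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_bundle(dir)
  expect_identical(back$encoding, pred$encoding)
  v1 <- predict(pred, probes)
  v2 <- predict(back, probes)
  expect_equal(v1$tier1_score, v2$tier1_score, tolerance = 1e-10)
  expect_identical(v1$family, v2$family)
  feats <- encode_dataset(probes, "coupled")$features
  for (f in names(pred$tier2)) {
    expect_equal(decision_value(pred$tier2[[f]], feats),
                 decision_value(back$tier2[[f]], feats), tolerance = 1e-10)
  }
})

test_that("incomplete or alien bundles fail with descriptive errors", {
  pred <- toy_predictor()
  dir <- tempfile("bundle")
  save_bundle(pred, dir)
  file.remove(file.path(dir, "tier2_HSP70.json"))
  expect_error(load_bundle(dir), "HSP70")
  empty <- tempfile("empty"); dir.create(empty)
  expect_error(load_bundle(empty), "manifest")
  # version mismatch is refused explicitly
  dir2 <- tempfile("bundle2")
  save_bundle(pred, dir2)
  mf <- file.path(dir2, "manifest.json")
  m <- jsonlite::read_json(mf)
  m$format_version <- "999"
  jsonlite::write_json(m, mf, auto_unbox = TRUE)
  expect_error(load_bundle(dir2), "version")
})

test_that("verdict TSV export keeps one labelled row per record", {
  pred <- toy_predictor()
  v <- predict(pred, toy_probe_records(10))
  f <- tempfile(fileext = ".tsv")
  write_verdicts_tsv(v, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 10L)
  expect_true(all(c("id", "is_hsp", "tier1_score", "family",
                    "confidence") %in% names(back)))
})
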