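test_that("output vocabularies have the documented sizes", {
  voc <- prescription_vocabularies()
  expect_length(voc$drug, 10)
  expect_length(voc$dosage, 14)
  expect_length(voc$frequency, 10)
  expect_true(all(c("Supportive Care Only", "Tiotropium") %in% voc$drug))
  expect_true(all(c("N/A", "1 puff (18 mcg)") %in% voc$dosage))
})

test_that("cohort generation honors size, quota, determinism, and clinical
           consistency", {
  cfg <- cohort_config(n = 500)
  co <- generate_cohort(cfg, seed = 3)
  expect_equal(nrow(co), 500)
  # exact comorbidity quota
  expect_equal(sum(co$renal_impaired | co$hepatic_impaired),
               round(500 * 0.15))
  # renal flag is equivalent to eGFR < 60
  expect_equal(co$renal_impaired, co$eGFR < 60)
  expect_true(all(co$eGFR > 0))
  expect_true(all(co$age >= 1 & co$age <= 95))
  # infants get bronchiolitis; COPD is adult-onset
  expect_true(all(co$age[co$diagnosis == "bronchiolitis"] <= 4))
  expect_true(all(co$age[co$diagnosis == "COPD"] >= 40))
  expect_true(all(co$smoking[co$age < 15] == "non-smoker"))
  # pure function of (config, seed)
  expect_identical(co, generate_cohort(cfg, seed = 3))
  expect_false(identical(co$diagnosis, generate_cohort(cfg, seed = 4)$diagnosis))
  expect_error(cohort_config(prevalence = c(COPD = 0.5)), "sum to 1")
})

test_that("renal dose adjustment follows the pharmacokinetic rule and snaps
           conservatively", {
  expect_equal(adjust_dose(500, 60), 500)       # min cap at full dose
  expect_equal(adjust_dose(500, 90), 500)
  expect_equal(adjust_dose(500, 30), 250)
  expect_true(all(adjust_dose(400, c(10, 45, 59, 61)) <= 400))
  expect_error(adjust_dose(-1, 50), "positive")
  expect_error(adjust_dose(500, 0), "positive")

  # brute-force snapping oracle over the plain mg classes
  mg <- c("0.5 mg" = 0.5, "100 mg" = 100, "250 mg" = 250, "400 mg" = 400,
          "500 mg" = 500)
  oracle_snap <- function(x) {
    d <- abs(mg - x)
    cands <- names(mg)[d == min(d)]
    cands[which.min(mg[cands])]                 # tie -> lower
  }
  for (x in c(250, 300, 175, 480, 50, 0.9)) {
    expect_equal(snap_to_dosage_class(x), oracle_snap(x), label = paste("mg", x))
  }
  # eGFR 45, base 400 -> raw 300 -> snapped by the nearest-lower rule
  expect_equal(snap_to_dosage_class(adjust_dose(400, 45)), oracle_snap(300))
})

test_that("prescription assignment obeys the formulary and its safety rules", {
  formulary <- load_formulary()
  interactions <- load_interactions()
  healthy <- list(age = 40, sex = "male", smoking = "non-smoker",
                  diagnosis = "healthy", comedication = "none",
                  renal_impaired = FALSE, hepatic_impaired = FALSE,
                  eGFR = 95, weight = 80)
  rx <- assign_prescription(healthy, formulary, interactions)
  expect_equal(rx, list(drug = "Supportive Care Only", dosage = "N/A",
                        frequency = "N/A"))

  # renal-impaired pneumonia adult: dosage class at or below the
  # non-impaired one (monotonicity of the adjustment rule)
  base <- assign_prescription(modifyList(healthy, list(diagnosis = "pneumonia")),
                              formulary, interactions)
  renal <- assign_prescription(modifyList(healthy, list(
    diagnosis = "pneumonia", renal_impaired = TRUE, eGFR = 32)),
    formulary, interactions)
  mg <- c("0.5 mg" = 0.5, "100 mg" = 100, "250 mg" = 250, "400 mg" = 400,
          "500 mg" = 500)
  expect_lt(mg[[renal$dosage]], mg[[base$dosage]] + 1e-9)
  expect_equal(renal$drug, base$drug)

  # doxycycline never below age 12
  child_lrti <- assign_prescription(modifyList(healthy, list(
    diagnosis = "LRTI", age = 8)), formulary, interactions)
  expect_false(child_lrti$drug == "Doxycycline")

  # interaction screen: anticoagulated LRTI adult is steered off doxycycline
  warf <- assign_prescription(modifyList(healthy, list(
    diagnosis = "LRTI", comedication = "Warfarin")), formulary, interactions)
  expect_equal(warf$drug, "Amoxicillin")

  # uncovered diagnosis is an explicit error
  expect_error(assign_prescription(modifyList(healthy, list(
    diagnosis = "influenza")), formulary, interactions), "influenza")
})

test_that("generated prescriptions stay inside the vocabularies and never
           emit a beta-blocker for asthma", {
  ds <- small_rx_split()$data
  voc <- prescription_vocabularies()
  expect_true(all(ds$drug %in% voc$drug))
  expect_true(all(ds$dosage %in% voc$dosage))
  expect_true(all(ds$frequency %in% voc$frequency))
  banned <- c("Propranolol", "Atenolol", "Metoprolol", "Carvedilol")
  expect_false(any(ds$drug[ds$diagnosis == "asthma"] %in% banned))
  # supportive care pairs with N/A dosing
  sco <- ds$drug == "Supportive Care Only"
  expect_true(all(ds$dosage[sco] == "N/A" & ds$frequency[sco] == "N/A"))
})

test_that("rare-pair oversampling lifts pairs to the threshold without
           touching originals", {
  ds <- small_rx_split()$train
  out <- oversample_rare(ds, threshold = 0.05, seed = 2)
  # originals untouched (row names aside, which rbind renumbers)
  expect_equal(out[seq_len(nrow(ds)), ], ds, ignore_attr = TRUE)
  target <- ceiling(0.05 * nrow(ds))
  pairs <- table(paste(out$diagnosis, out$drug))
  expect_true(all(pairs >= min(target, min(table(paste(ds$diagnosis, ds$drug))
                                           + target))))
  for (p in names(pairs)) expect_gte(pairs[[p]], target)
  # synthetic ages lie within their parent pair's range
  syn <- out[grepl("_s", out$id), ]
  for (p in unique(paste(syn$diagnosis, syn$drug))) {
    orig_ages <- ds$age[paste(ds$diagnosis, ds$drug) == p]
    syn_ages <- syn$age[paste(syn$diagnosis, syn$drug) == p]
    expect_true(all(syn_ages >= min(orig_ages) - 2 &
                      syn_ages <= max(orig_ages) + 2))
  }
  # a dataset with a single (diagnosis, drug) pair has no rare pair
  dense <- ds[ds$diagnosis == "COPD" & ds$drug == "Tiotropium", ]
  expect_identical(oversample_rare(dense, threshold = 0.05, seed = 1), dense)
})

test_that("the joint-label forest memorizes the noiseless rule cohort and is
           seed-stable", {
  sp <- small_rx_split()
  mod <- train_recommender(sp$train, seed = 0)
  expect_equal(mod$config$trees, 500)
  expect_equal(mod$config$max_depth, 15)
  expect_equal(mod$config$min_samples_leaf, 2)
  # labels are a deterministic function of features, so the forest
  # memorizes the training set up to the 2-sample leaf-size floor
  pr <- predict_recommender(mod, sp$train)
  expect_gte(mean(pr$drug == sp$train$drug), 0.995)

  accs <- vapply(0:2, function(s) {
    m <- train_recommender(sp$train, seed = s)
    mean(predict_recommender(m, sp$test)$drug == sp$test$drug)
  }, 0)
  expect_lt(max(accs) - min(accs), 0.01)
  expect_error(train_recommender(sp$train[, setdiff(names(sp$train), "dosage")]),
               "dosage")
})

test_that("evaluation reports partition support and flag low confidence", {
  sp <- small_rx_split()
  mod <- train_recommender(sp$train, seed = 0)
  ev <- evaluate_recommender(mod, sp$test)
  for (rp in ev$reports) {
    expect_named(rp, c("class", "precision", "recall", "f1", "support"))
    # support column sums to the test size (macro/weighted rows echo it)
    expect_equal(rp$support[rp$class == "macro avg"], nrow(sp$test))
    expect_equal(sum(rp$support[!rp$class %in% c("macro avg", "weighted avg")]),
                 nrow(sp$test))
  }
  expect_true(all(ev$accuracy >= 0 & ev$accuracy <= 1))
  expect_gte(ev$n_flagged, 0)
  expect_error(evaluate_recommender(mod, sp$test[0, ]), "empty")
})

test_that("safety invariants hold on a large generated sample", {
  # 10,000 prescriptions: adjusted dose never exceeds base; contraindicated
  # pairs never appear; renal-impaired never get the unadjusted class of a
  # renally-cleared drug when a lower class exists
  ds <- generate_prescribing_dataset(cohort_config(n = 10000), seed = 42)
  expect_false(any(ds$drug[ds$diagnosis == "asthma"] %in%
                     c("Propranolol", "Atenolol", "Metoprolol", "Carvedilol")))
  expect_false(any(ds$drug == "Ibuprofen" & ds$renal_impaired))
  expect_false(any(ds$drug == "Doxycycline" & ds$age < 12))
  mg <- c("0.5 mg" = 0.5, "100 mg" = 100, "250 mg" = 250, "400 mg" = 400,
          "500 mg" = 500)
  renal_az <- ds$drug == "Azithromycin" & ds$renal_impaired &
    ds$dosage %in% names(mg) & ds$age >= 12
  # formulary base for adult azithromycin is 500 mg (pneumonia) or 250 mg
  # (bronchiectasis); the adjusted class can never exceed the base
  base_mg <- ifelse(ds$diagnosis[renal_az] == "pneumonia", 500, 250)
  expect_true(all(mg[ds$dosage[renal_az]] <= base_mg))
  # and matches the rule exactly: snap(base * min(1, eGFR/60))
  expected <- vapply(which(renal_az), function(i) {
    b <- if (ds$diagnosis[i] == "pneumonia") 500 else 250
    snap_to_dosage_class(adjust_dose(b, ds$eGFR[i]))
  }, "")
  expect_equal(ds$dosage[renal_az], expected)
})
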