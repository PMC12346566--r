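# Synthetic prescribing cohort and the multi-output drug/dosage/frequency
# recommender. Labels are generated by an explicit clinical rule engine
# (formulary + contraindication + interaction + renal-adjustment rules), so
# held-out performance approaching 1 is a property of the synthetic design,
# not evidence of clinical validity.

#' Output vocabularies of the recommender
#'
#' The ten drug categories, fourteen dosage classes, and ten administration
#' frequencies the prescription engine works over. Range-style dosage labels
#' are opaque class names.
#'
#' @return Named list with `drug`, `dosage`, `frequency` character vectors.
#' @export
prescription_vocabularies <- function() {
  list(
    drug = c("Albuterol", "Amoxicillin", "Azithromycin", "Budesonide",
             "Doxycycline", "Fluticasone", "Hypertonic Saline", "Ibuprofen",
             "Supportive Care Only", "Tiotropium"),
    dosage = c("0.5 mg", "0.63-1.25 mg", "1 puff (18 mcg)", "10 mg/kg",
               "100 mg", "2 puffs", "250 mg", "4 mL of 7% saline", "400 mg",
               "400-600 mg", "500 mg", "88 mcg", "90 mg/kg/day", "N/A"),
    frequency = c("3 to 4 times", "Divided in 2 doses", "Every 4 to 6 h (PRN)",
                  "Every 6 to 8 h (PRN)", "Every 8 h", "N/A", "Once daily",
                  "Once daily for 3-5 days", "Twice daily",
                  "Twice daily for 7-14 days")
  )
}

# plain single-value mg dosage classes eligible for renal snapping
.mg_classes <- c("0.5 mg" = 0.5, "100 mg" = 100, "250 mg" = 250,
                 "400 mg" = 400, "500 mg" = 500)

#' Load the formulary rule table
#'
#' @param path YAML path; defaults to the packaged formulary.
#' @return A `formulary` list (age bands, rules, contraindications,
#'   renally-cleared drugs); vocabulary closure is validated.
#' @export
load_formulary <- function(path = system.file("extdata", "formulary.yaml",
                                              package = "lungrx")) {
  y <- yaml::read_yaml(path)
  voc <- prescription_vocabularies()
  for (dx in names(y$rules)) {
    for (band in names(y$rules[[dx]])) {
      r <- y$rules[[dx]][[band]]
      if (!r$drug %in% voc$drug || !r$dosage %in% voc$dosage ||
          !r$frequency %in% voc$frequency) {
        stop("formulary rule outside the output vocabularies: ", dx, "/", band)
      }
    }
  }
  structure(y, class = "formulary")
}

#' Load the drug-interaction screen
#' @param path YAML path; defaults to the packaged 25-pair table.
#' @return An `interaction_table` list.
#' @export
load_interactions <- function(path = system.file("extdata", "interactions.yaml",
                                                 package = "lungrx")) {
  y <- yaml::read_yaml(path)
  if (length(y$pairs) != 25) {
    warning("interaction table has ", length(y$pairs), " pairs (expected 25)")
  }
  structure(y, class = "interaction_table")
}

#' Renal pharmacokinetic dose adjustment
#'
#' `adjusted = base * min(1, eGFR / 60)`: full dose at or above an eGFR of
#' 60 mL/min/1.73m2, linear reduction below it.
#'
#' @param base Base dose (same units returned); must be positive.
#' @param eGFR Estimated glomerular filtration rate (mL/min/1.73m2),
#'   positive.
#' @return Adjusted numeric dose, never above `base`.
#' @export
adjust_dose <- function(base, eGFR) {
  if (any(base <= 0)) stop("adjust_dose: base dose must be positive")
  if (any(eGFR <= 0)) stop("adjust_dose: eGFR must be positive")
  base * pmin(1, eGFR / 60)
}

#' Snap a milligram dose to the nearest dosage class
#'
#' Candidates are the plain single-value mg classes; ties go to the lower
#' class (the conservative choice for renal dosing).
#'
#' @param mg Numeric dose in milligrams.
#' @return A dosage class label.
#' @export
snap_to_dosage_class <- function(mg) {
  d <- abs(.mg_classes - mg)
  # ties -> lower class: order by (distance, class value)
  names(.mg_classes)[order(d, .mg_classes)][1]
}

#' Cohort configuration
#'
#' @param n Number of virtual patient records (default 2000).
#' @param comorbidity_rate Share of records carrying renal and/or hepatic
#'   impairment, sampled as an exact quota (default 0.15).
#' @param prevalence Named diagnosis probabilities summing to 1. The default
#'   is respiratory-burden-weighted so that every formulary drug draws
#'   non-zero support at the default `n`.
#' @param anticoagulant_rate Probability that an adult aged 65+ is on an
#'   anticoagulant (halved for 40-64; zero below 40).
#' @param label_noise Probability of re-drawing a record's drug uniformly
#'   (default 0: labels are a pure function of features).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n = 2000, comorbidity_rate = 0.15,
                          prevalence = c(COPD = 0.30, asthma = 0.20,
                                         URTI = 0.15, pneumonia = 0.12,
                                         healthy = 0.10, bronchiolitis = 0.06,
                                         bronchiectasis = 0.04, LRTI = 0.03),
                          anticoagulant_rate = 0.10, label_noise = 0) {
  if (abs(sum(prevalence) - 1) > 1e-8) stop("prevalence must sum to 1")
  if (!all(names(prevalence) %in% diagnosis_classes())) {
    stop("prevalence names must be diagnosis classes")
  }
  stopifnot(n >= 1, comorbidity_rate >= 0, comorbidity_rate <= 1,
            label_noise >= 0, label_noise <= 1)
  structure(list(n = n, comorbidity_rate = comorbidity_rate,
                 prevalence = prevalence,
                 anticoagulant_rate = anticoagulant_rate,
                 label_noise = label_noise), class = "cohort_config")
}

# diagnosis-conditional age ranges (years)
.age_ranges <- list(
  asthma = c(3, 80), bronchiectasis = c(10, 90), bronchiolitis = c(1, 4),
  COPD = c(40, 90), healthy = c(1, 95), LRTI = c(1, 95),
  pneumonia = c(1, 95), URTI = c(1, 95))

#' Generate the synthetic patient cohort
#'
#' Exactly `n` records with randomized demographics: diagnosis drawn from the
#' prevalence vector with diagnosis-appropriate age ranges (bronchiolitis is
#' an infant disease; COPD is adult-onset), sex, smoking status (age 15+),
#' anticoagulant co-medication, and an exact-quota comorbidity share of
#' renal/hepatic impairment. eGFR is Uniform(15, 59) for renal-impaired
#' records and Normal(95, 15) truncated at 60 otherwise, so
#' `renal_impaired == (eGFR < 60)` by construction.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the cohort is a pure function of
#'   `(config, seed)`.
#' @return Data frame with one row per patient.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 0) {
  n <- config$n
  with_seed(seed * 2003L + 11L, {
    dx <- sample(names(config$prevalence), n, replace = TRUE,
                 prob = config$prevalence)
    age <- vapply(dx, function(d) {
      r <- .age_ranges[[d]]
      sample(r[1]:r[2], 1)
    }, 0L)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    smoking <- ifelse(age >= 15 & stats::runif(n) < 0.25, "smoker", "non-smoker")
    ac_prob <- ifelse(age >= 65, config$anticoagulant_rate,
                      ifelse(age >= 40, config$anticoagulant_rate / 2, 0))
    anticoagulants <- c("Warfarin", "Apixaban", "Rivaroxaban", "Dabigatran",
                        "Enoxaparin")
    comedication <- ifelse(stats::runif(n) < ac_prob,
                           sample(anticoagulants, n, replace = TRUE), "none")

    # exact comorbidity quota
    n_comorbid <- round(n * config$comorbidity_rate)
    comorbid_idx <- sample(n, n_comorbid)
    renal <- logical(n); hepatic <- logical(n)
    renal[comorbid_idx] <- stats::runif(n_comorbid) < 0.6
    hepatic[comorbid_idx] <- stats::runif(n_comorbid) < 0.5
    neither <- comorbid_idx[!renal[comorbid_idx] & !hepatic[comorbid_idx]]
    renal[neither] <- TRUE                      # quota members carry >= 1 flag

    eGFR <- numeric(n)
    eGFR[renal] <- stats::runif(sum(renal), 15, 59)
    k <- sum(!renal)
    g <- stats::rnorm(k, 95, 15)
    while (any(g < 60)) g[g < 60] <- stats::rnorm(sum(g < 60), 95, 15)
    eGFR[!renal] <- g

    weight <- ifelse(age < 18, pmin(8 + 2.3 * age, 60),
                     pmin(pmax(stats::rnorm(n, 75, 12), 45), 120))

    data.frame(
      id = sprintf("P%05d", seq_len(n)),
      age = as.integer(age), sex = sex, smoking = smoking,
      diagnosis = dx, comedication = comedication,
      renal_impaired = renal, hepatic_impaired = hepatic,
      eGFR = round(eGFR, 1), weight = round(weight, 1),
      stringsAsFactors = FALSE, row.names = NULL)
  })
}

.age_band <- function(age, bands) {
  for (b in names(bands)) {
    if (age >= bands[[b]][1] && age <= bands[[b]][2]) return(b)
  }
  stop("age ", age, " outside all formulary age bands")
}

#' Assign a prescription to one patient record
#'
#' Rule order: formulary lookup by (diagnosis, age band, smoking override);
#' contraindication screen (class-level exclusions such as beta-blockers in
#' asthma, and conditional alternates such as NSAIDs under renal impairment
#' or tetracyclines under age 12); the 25-pair interaction screen against the
#' patient's co-medication; finally renal dose adjustment for renally-cleared
#' drugs, snapped to the nearest (tie: lower) mg dosage class.
#'
#' @param rec A one-row data frame (or list) with the [generate_cohort()]
#'   fields.
#' @param formulary A [load_formulary()] table.
#' @param interactions A [load_interactions()] table.
#' @return List with `drug`, `dosage`, `frequency`.
#' @export
assign_prescription <- function(rec, formulary = load_formulary(),
                                interactions = load_interactions()) {
  band <- .age_band(rec$age, formulary$age_bands)
  rules <- formulary$rules[[rec$diagnosis]]
  if (is.null(rules)) stop("formulary does not cover diagnosis ", rec$diagnosis)
  smoker_key <- paste0(band, "_smoker")
  r <- if (identical(rec$smoking, "smoker") && !is.null(rules[[smoker_key]])) {
    rules[[smoker_key]]
  } else {
    rules[[band]]
  }
  if (is.null(r)) stop("formulary does not cover (", rec$diagnosis, ", ", band, ")")
  rx <- list(drug = r$drug, dosage = r$dosage, frequency = r$frequency)

  # contraindication screen
  for (ct in formulary$contraindications) {
    if (!is.null(ct$avoid_class)) {
      banned <- formulary$drug_classes[[ct$avoid_class]]
      if (identical(rec$diagnosis, ct$diagnosis) && rx$drug %in% banned) {
        stop("contraindicated class reached the formulary output for ",
             rec$diagnosis)
      }
    } else if (identical(rx$drug, ct$drug)) {
      hit <- switch(ct$when,
                    renal_impaired = isTRUE(rec$renal_impaired),
                    hepatic_impaired = isTRUE(rec$hepatic_impaired),
                    age_lt_12 = rec$age < 12,
                    FALSE)
      if (hit) rx <- ct$alternate
    }
  }

  # interaction screen (25-pair lookup against co-medication)
  if (!identical(rec$comedication, "none")) {
    hits <- function(drug) any(vapply(interactions$pairs, function(p) {
      identical(p$a, rec$comedication) && identical(p$b, drug)
    }, TRUE))
    if (hits(rx$drug)) {
      alt <- interactions$alternates[[rx$drug]]
      rx <- if (!is.null(alt) && !hits(alt$drug)) alt else
        list(drug = "Supportive Care Only", dosage = "N/A", frequency = "N/A")
    }
  }

  # renal dose adjustment for renally-cleared mg dosing
  if (isTRUE(rec$renal_impaired) && rx$drug %in% formulary$renal_cleared &&
      rx$dosage %in% names(.mg_classes)) {
    adj <- adjust_dose(.mg_classes[[rx$dosage]], rec$eGFR)
    rx$dosage <- snap_to_dosage_class(adj)
  }
  rx
}

#' Generate the fully labelled prescribing dataset
#'
#' Cohort generation, rule-based prescription assignment, optional label
#' noise, and a final row shuffle.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param formulary,interactions Rule tables.
#' @return Data frame: cohort fields plus `drug`, `dosage`, `frequency`.
#' @export
generate_prescribing_dataset <- function(config = cohort_config(), seed = 0,
                                         formulary = load_formulary(),
                                         interactions = load_interactions()) {
  cohort <- generate_cohort(config, seed)
  rx <- lapply(seq_len(nrow(cohort)), function(i) {
    assign_prescription(cohort[i, ], formulary, interactions)
  })
  cohort$drug <- vapply(rx, `[[`, "", "drug")
  cohort$dosage <- vapply(rx, `[[`, "", "dosage")
  cohort$frequency <- vapply(rx, `[[`, "", "frequency")
  with_seed(seed * 977L + 5L, {
    if (config$label_noise > 0) {
      flip <- stats::runif(nrow(cohort)) < config$label_noise
      cohort$drug[flip] <- sample(prescription_vocabularies()$drug,
                                  sum(flip), replace = TRUE)
    }
    cohort[sample(nrow(cohort)), , drop = FALSE]
  })
}

#' Oversample rare diagnosis-drug pairs (mixed-type SMOTE)
#'
#' Every `(diagnosis, drug)` pair below `threshold` prevalence is
#' synthetically oversampled up to the threshold count: numeric features
#' (age, eGFR, weight) are interpolated between same-pair neighbours,
#' categorical features and the three targets are copied from the nearer
#' neighbour, and single-row pairs fall back to duplication with age jitter.
#' Original rows are untouched. Apply to the training partition only.
#'
#' @param rows Labelled data frame from [generate_prescribing_dataset()].
#' @param threshold Minimum pair prevalence (default 0.05).
#' @param seed Integer seed.
#' @return The augmented data frame (synthetic rows appended, ids suffixed
#'   `_s<k>`).
#' @export
oversample_rare <- function(rows, threshold = 0.05, seed = 0) {
  stopifnot(threshold > 0, threshold < 1)
  num_cols <- c("age", "eGFR", "weight")
  pair_id <- paste(rows$diagnosis, rows$drug, sep = ".")
  pair <- factor(pair_id, levels = unique(pair_id))      # locale-stable
  target_n <- ceiling(threshold * nrow(rows))
  out <- list()
  with_seed(seed * 389L + 3L, {
    for (p in levels(pair)) {
      ix <- which(pair == p)
      need <- target_n - length(ix)
      if (need <= 0) next
      for (k in seq_len(need)) {
        a <- rows[ix[sample.int(length(ix), 1)], , drop = FALSE]
        if (length(ix) == 1) {
          syn <- a
          syn$age <- max(1L, min(95L, a$age + sample(-2:2, 1)))
        } else {
          # nearest same-pair neighbour in standardized numeric space
          others <- rows[setdiff(ix, which(rows$id == a$id)), , drop = FALSE]
          sc <- vapply(num_cols, function(cc) stats::sd(rows[[cc]][ix]) + 1e-6, 0)
          dmat <- sweep(as.matrix(others[num_cols]), 2,
                        as.numeric(a[num_cols]))
          d <- sqrt(rowSums(sweep(dmat, 2, sc, `/`)^2))
          b <- others[which.min(d), , drop = FALSE]
          gam <- stats::runif(1)
          syn <- if (gam < 0.5) a else b       # categoricals + targets: nearer
          for (cc in num_cols) {
            syn[[cc]] <- a[[cc]] + gam * (b[[cc]] - a[[cc]])
          }
          syn$age <- as.integer(round(syn$age))
        }
        syn$id <- paste0(a$id, "_s", k)
        out[[length(out) + 1L]] <- syn
      }
    }
  })
  if (length(out) == 0) return(rows)
  rbind(rows, do.call(rbind, out))
}

#' Recommender configuration
#'
#' @param trees Number of decision trees (500).
#' @param max_depth Maximum tree depth (15).
#' @param min_samples_leaf Minimum samples per leaf (2).
#' @param criterion Split criterion (`"gini"`).
#' @return A `recommender_config` list.
#' @export
recommender_config <- function(trees = 500, max_depth = 15,
                               min_samples_leaf = 2, criterion = "gini") {
  structure(list(trees = trees, max_depth = max_depth,
                 min_samples_leaf = min_samples_leaf, criterion = criterion),
            class = "recommender_config")
}

.rx_feature_matrix <- function(rows, age_center = NULL, age_scale = NULL) {
  fac <- data.frame(
    diagnosis = factor(rows$diagnosis, levels = diagnosis_classes()),
    sex = factor(rows$sex, levels = c("female", "male")),
    smoking = factor(rows$smoking, levels = c("non-smoker", "smoker")),
    comedication = factor(ifelse(rows$comedication == "none", "none",
                                 "anticoagulant"),
                          levels = c("none", "anticoagulant")))
  oh <- stats::model.matrix(~ . - 1, fac)
  if (is.null(age_center)) {
    age_center <- mean(rows$age); age_scale <- stats::sd(rows$age) + 1e-9
  }
  X <- cbind(oh, age = (rows$age - age_center) / age_scale,
             eGFR = rows$eGFR, weight = rows$weight,
             renal_impaired = as.numeric(rows$renal_impaired),
             hepatic_impaired = as.numeric(rows$hepatic_impaired))
  list(X = X, age_center = age_center, age_scale = age_scale)
}

#' Train the multi-output prescription recommender
#'
#' One random-forest ensemble jointly predicting all three targets: the
#' forest classifies the joint `drug | dosage | frequency` label and
#' predictions are decoded back into the three output domains. Features are
#' one-hot-encoded categoricals plus standardized age and raw eGFR/weight.
#'
#' @param rows Training rows (after any [oversample_rare()]).
#' @param config A [recommender_config()].
#' @param seed Integer seed.
#' @return A `prescription_recommender`.
#' @export
train_recommender <- function(rows, config = recommender_config(), seed = 0) {
  for (cc in c("drug", "dosage", "frequency")) {
    if (is.null(rows[[cc]])) stop("missing target column: ", cc)
  }
  fm <- .rx_feature_matrix(rows)
  joint <- factor(paste(rows$drug, rows$dosage, rows$frequency, sep = " | "))
  fit <- ranger::ranger(
    x = fm$X, y = joint,
    num.trees = config$trees,
    max.depth = config$max_depth,
    min.node.size = config$min_samples_leaf,
    splitrule = config$criterion,
    probability = TRUE,
    seed = seed,
    num.threads = 1)
  structure(list(forest = fit, config = config,
                 joint_levels = levels(joint),
                 age_center = fm$age_center, age_scale = fm$age_scale),
            class = "prescription_recommender")
}

#' Predict prescriptions for patient rows
#'
#' @param model A [train_recommender()] model.
#' @param rows Patient rows (cohort fields).
#' @param confidence_threshold Joint-class probability below which a
#'   prediction is flagged for review (default 0.5).
#' @return Data frame with `drug`, `dosage`, `frequency`, `confidence`,
#'   `flagged`.
#' @export
predict_recommender <- function(model, rows, confidence_threshold = 0.5) {
  fm <- .rx_feature_matrix(rows, model$age_center, model$age_scale)
  if (!identical(colnames(fm$X),
                 model$forest$forest$independent.variable.names)) {
    stop("feature mismatch between rows and model")
  }
  P <- stats::predict(model$forest, data = fm$X, num.threads = 1)$predictions
  best <- max.col(P, ties.method = "first")
  conf <- P[cbind(seq_len(nrow(P)), best)]
  parts <- strsplit(colnames(P)[best], " | ", fixed = TRUE)
  data.frame(
    drug = vapply(parts, `[[`, "", 1),
    dosage = vapply(parts, `[[`, "", 2),
    frequency = vapply(parts, `[[`, "", 3),
    confidence = conf,
    flagged = conf < confidence_threshold,
    stringsAsFactors = FALSE)
}

#' Evaluate the recommender on held-out rows
#'
#' Produces one classification report per output domain (per-class
#' precision/recall/F1/support plus macro and weighted averages), overall
#' per-target accuracies, and the low-confidence review flags.
#'
#' @param model A [train_recommender()] model.
#' @param test_rows Held-out labelled rows.
#' @return List with `reports` (drug/dosage/frequency data frames),
#'   `accuracy` (named vector), `predictions`, `n_flagged`.
#' @export
evaluate_recommender <- function(model, test_rows) {
  if (nrow(test_rows) == 0) stop("evaluate_recommender: empty test set")
  pred <- predict_recommender(model, test_rows)
  voc <- prescription_vocabularies()
  reports <- list(
    drug = classification_report(test_rows$drug, pred$drug, voc$drug),
    dosage = classification_report(test_rows$dosage, pred$dosage, voc$dosage),
    frequency = classification_report(test_rows$frequency, pred$frequency,
                                      voc$frequency))
  acc <- c(drug = mean(pred$drug == test_rows$drug),
           dosage = mean(pred$dosage == test_rows$dosage),
           frequency = mean(pred$frequency == test_rows$frequency))
  list(reports = reports, accuracy = acc, predictions = pred,
       n_flagged = sum(pred$flagged))
}

#' Stratified train/test split of a labelled dataset
#'
#' 80/20 by default, stratified on the drug target.
#'
#' @param rows Labelled data frame.
#' @param test_fraction Held-out share (default 0.2).
#' @param seed Integer seed.
#' @return List with `train` and `test` data frames.
#' @export
split_prescribing_dataset <- function(rows, test_fraction = 0.2, seed = 0) {
  with_seed(seed * 151L + 13L, {
    grp <- factor(rows$drug, levels = unique(rows$drug))   # locale-stable
    test_idx <- unlist(lapply(split(seq_len(nrow(rows)), grp),
                              function(ix) {
      sample(ix, round(length(ix) * test_fraction))
    }), use.names = FALSE)
    list(train = rows[-test_idx, , drop = FALSE],
         test = rows[test_idx, , drop = FALSE])
  })
}
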