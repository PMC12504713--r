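#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions emulated by [simulate_cohort()]: a Gaussian
#' mixture in embedding space with planted tile clusters, per-patient
#' Dirichlet compositions over those clusters, a histological subtype whose
#' log-odds are linear in the clr (centred log-ratio) coordinates of the true
#' composition, and exponential survival whose log-hazard is linear in the
#' same coordinates, with independent administrative censoring.
#'
#' @param seed master seed; every stochastic step derives a named substream
#'   from it, so adding a generator call never perturbs other outputs.
#' @param n_components number of planted embedding clusters (>= 2).
#' @param dim embedding dimensionality (default 128, matching common
#'   self-supervised pathology encoders).
#' @param n_patients number of patients; 0 yields empty tables with headers.
#' @param slides_per_patient integer range `c(min, max)` of slides per patient.
#' @param tiles_per_slide integer range `c(min, max)` of tiles per slide.
#' @param component_separation centroid spacing in units of the (unit)
#'   within-component standard deviation; must be positive.
#' @param dirichlet_concentration symmetric Dirichlet concentration for
#'   patient compositions (smaller = more uneven compositions).
#' @param subtype_drivers named numeric vector of log-odds effects per clr
#'   unit; names are 0-based component indices, e.g. `c("2" = 1.5)`.
#' @param survival_drivers named numeric vector of log-hazard effects per clr
#'   unit, same naming convention.
#' @param subtype_intercept intercept of the subtype logit; the default -1.1
#'   gives roughly a 1:3 non-epithelioid:epithelioid ratio at zero effects,
#'   the imbalance typical of surgical mesothelioma series.
#' @param baseline_hazard baseline event rate per month; the default 0.045
#'   corresponds to a median survival near 15 months at zero effects.
#' @param censoring_fraction target fraction of censored patients in `[0, 1]`.
#' @param agreement_level default rater agreement for [simulate_ratings()].
#' @return a validated `synthetic_config` list.
#' @seealso [simulate_cohort()]
#' @export
synthetic_config <- function(seed = 1L,
                             n_components = 10L,
                             dim = 128L,
                             n_patients = 200L,
                             slides_per_patient = c(1L, 3L),
                             tiles_per_slide = c(150L, 400L),
                             component_separation = 6,
                             dirichlet_concentration = 1,
                             subtype_drivers = numeric(0),
                             survival_drivers = numeric(0),
                             subtype_intercept = -1.1,
                             baseline_hazard = 0.045,
                             censoring_fraction = 0.2,
                             agreement_level = 0.8) {
  cfg <- list(
    seed = as.integer(seed), n_components = as.integer(n_components),
    dim = as.integer(dim), n_patients = as.integer(n_patients),
    slides_per_patient = as.integer(slides_per_patient),
    tiles_per_slide = as.integer(tiles_per_slide),
    component_separation = component_separation,
    dirichlet_concentration = dirichlet_concentration,
    subtype_drivers = subtype_drivers, survival_drivers = survival_drivers,
    subtype_intercept = subtype_intercept, baseline_hazard = baseline_hazard,
    censoring_fraction = censoring_fraction, agreement_level = agreement_level
  )
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  stopifnot(
    cfg$n_components >= 2, cfg$dim >= 2, cfg$n_patients >= 0,
    length(cfg$slides_per_patient) == 2,
    cfg$slides_per_patient[1] >= 1,
    cfg$slides_per_patient[1] <= cfg$slides_per_patient[2],
    length(cfg$tiles_per_slide) == 2,
    cfg$tiles_per_slide[1] >= 1,
    cfg$tiles_per_slide[1] <= cfg$tiles_per_slide[2],
    cfg$dirichlet_concentration > 0,
    cfg$baseline_hazard > 0,
    cfg$censoring_fraction >= 0, cfg$censoring_fraction <= 1,
    cfg$agreement_level >= 0, cfg$agreement_level <= 1
  )
  if (!is.numeric(cfg$component_separation) || cfg$component_separation <= 0) {
    stop("component_separation must be a positive number")
  }
  for (dr in list(cfg$subtype_drivers, cfg$survival_drivers)) {
    if (length(dr)) {
      idx <- suppressWarnings(as.integer(names(dr)))
      if (anyNA(idx) || any(idx < 0) || any(idx >= cfg$n_components)) {
        stop("driver names must be 0-based component indices below n_components")
      }
    }
  }
  invisible(cfg)
}

# Component centroids with pairwise Euclidean distance exactly `sep` when the
# embedding dimension allows an orthogonal placement; otherwise random
# directions rescaled so the minimum pairwise spacing equals `sep`.
component_centroids <- function(n_components, dim, sep, seed) {
  if (dim >= n_components) {
    cent <- matrix(0, n_components, dim)
    cent[cbind(seq_len(n_components), seq_len(n_components))] <- sep / sqrt(2)
  } else {
    cent <- with_substream(seed, "centroids",
      matrix(rnorm(n_components * dim), n_components, dim))
    dmin <- min(dist(cent))
    cent <- cent * (sep / dmin)
  }
  cent
}

# uniform integers in [lo, hi]; safe when lo == hi (sample() would otherwise
# treat a length-1 vector as 1:x)
sample_range <- function(range, n) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

rdirichlet_rows <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

driver_vector <- function(drivers, n_components) {
  beta <- numeric(n_components)
  if (length(drivers)) beta[as.integer(names(drivers)) + 1L] <- drivers
  beta
}

#' Simulate a synthetic tile-embedding cohort with known ground truth
#'
#' Draws tile embeddings from an isotropic unit-variance Gaussian mixture,
#' assembles them into slides and patients, and generates clinical outcomes
#' driven by each patient's true composition on the clr scale. Censoring is
#' administrative: an independent uniform censoring time whose upper bound is
#' solved numerically so the expected censored fraction matches the target.
#'
#' @param config a [synthetic_config()].
#' @return list with elements
#'   * `tiles`: data frame `tile_id`, `slide_id`, `patient_id`, `e0..e{D-1}`;
#'   * `patients`: data frame `patient_id`, `subtype`
#'     (epithelioid/biphasic/sarcomatoid), `time_months`, `event`;
#'   * `truth`: planted `tile_component` (0-based, named by tile id),
#'     `patient_composition` (rows sum to 1), the clr-scale
#'     `true_subtype_coefficients` and `true_survival_coefficients`,
#'     `centroids`, and the solved censoring bound `censor_upper`.
#' @export
simulate_cohort <- function(config) {
  validate_synthetic_config(config)
  C <- config$n_components
  D <- config$dim
  cent <- component_centroids(C, D, config$component_separation, config$seed)
  emb_names <- paste0("e", seq_len(D) - 1L)

  if (config$n_patients == 0L) {
    tiles <- as.data.frame(c(
      list(tile_id = character(0), slide_id = character(0),
           patient_id = character(0)),
      setNames(rep(list(numeric(0)), D), emb_names)
    ))
    patients <- data.frame(patient_id = character(0), subtype = character(0),
                           time_months = numeric(0), event = logical(0))
    truth <- list(tile_component = setNames(integer(0), character(0)),
                  patient_composition = matrix(numeric(0), 0, C),
                  true_subtype_coefficients = driver_vector(config$subtype_drivers, C),
                  true_survival_coefficients = driver_vector(config$survival_drivers, C),
                  centroids = cent, censor_upper = NA_real_)
    return(list(tiles = tiles, patients = patients, truth = truth))
  }

  n_pat <- config$n_patients
  patient_id <- sprintf("p%04d", seq_len(n_pat))

  comp <- with_substream(config$seed, "composition",
    rdirichlet_rows(n_pat, rep(config$dirichlet_concentration, C)))
  rownames(comp) <- patient_id
  colnames(comp) <- paste0("hpc_", seq_len(C) - 1L)

  # tiles: slides and per-tile components drawn from the patient composition
  tiles <- with_substream(config$seed, "tiles", {
    n_slides <- sample_range(config$slides_per_patient, n_pat)
    rows <- vector("list", n_pat)
    for (i in seq_len(n_pat)) {
      per_slide <- sample_range(config$tiles_per_slide, n_slides[i])
      slide_id <- rep(sprintf("%s_s%d", patient_id[i], seq_len(n_slides[i])),
                      per_slide)
      k <- sum(per_slide)
      tc <- sample.int(C, k, replace = TRUE, prob = comp[i, ])
      rows[[i]] <- data.frame(patient_id = patient_id[i], slide_id = slide_id,
                              component = tc - 1L)
    }
    meta <- do.call(rbind, rows)
    n_tiles <- nrow(meta)
    emb <- matrix(rnorm(n_tiles * D), n_tiles, D) + cent[meta$component + 1L, ]
    colnames(emb) <- emb_names
    cbind(data.frame(tile_id = sprintf("t%07d", seq_len(n_tiles)),
                     slide_id = meta$slide_id, patient_id = meta$patient_id,
                     component = meta$component),
          as.data.frame(emb))
  })
  tile_component <- setNames(tiles$component, tiles$tile_id)
  tiles$component <- NULL

  clr_true <- clr_transform(comp)
  beta_sub <- driver_vector(config$subtype_drivers, C)
  beta_sur <- driver_vector(config$survival_drivers, C)

  subtype <- with_substream(config$seed, "subtype", {
    logit <- config$subtype_intercept + drop(clr_true %*% beta_sub)
    y <- rbinom(n_pat, 1L, plogis(logit))
    ifelse(y == 1L, sample(c("biphasic", "sarcomatoid"), n_pat, replace = TRUE),
           "epithelioid")
  })

  rate <- config$baseline_hazard * exp(drop(clr_true %*% beta_sur))
  t_event <- with_substream(config$seed, "survival", rexp(n_pat, rate))
  censor_upper <- NA_real_
  if (config$censoring_fraction > 0) {
    # P(censored | rate) for C ~ U(0, tau): (1 - exp(-rate*tau)) / (rate*tau)
    cens_frac <- function(log_tau) {
      tau <- exp(log_tau)
      mean((1 - exp(-rate * tau)) / (rate * tau)) - config$censoring_fraction
    }
    censor_upper <- exp(uniroot(cens_frac, c(-10, 15))$root)
    t_cens <- with_substream(config$seed, "censor", runif(n_pat, 0, censor_upper))
    event <- t_event <= t_cens
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(TRUE, n_pat)
    time <- t_event
  }

  patients <- data.frame(patient_id = patient_id, subtype = subtype,
                         time_months = time, event = event)
  truth <- list(tile_component = tile_component, patient_composition = comp,
                true_subtype_coefficients = beta_sub,
                true_survival_coefficients = beta_sur,
                centroids = cent, censor_upper = censor_upper)
  list(tiles = tiles, patients = patients, truth = truth)
}

#' Simulate a multi-rater categorical annotation table
#'
#' Each item carries a latent true category; each rater reports it with
#' probability `agreement_level` and otherwise picks uniformly among the
#' remaining categories. The result is an item-by-category count table of the
#' kind summarised by [fleiss_kappa()] and [majority_consensus()].
#'
#' @param n_items,n_raters,n_categories table geometry (`n_raters >= 2`,
#'   `n_categories >= 2`).
#' @param agreement_level probability in `[0, 1]` of reporting the truth;
#'   `1/n_categories` makes ratings uninformative (kappa near 0).
#' @param seed RNG seed.
#' @return integer matrix `n_items x n_categories`, every row summing to
#'   `n_raters`, with the latent truth in `attr(, "truth")` (0-based).
#' @export
simulate_ratings <- function(n_items, n_raters, n_categories,
                             agreement_level, seed = 1L) {
  stopifnot(n_items >= 1, n_raters >= 2, n_categories >= 2,
            agreement_level >= 0, agreement_level <= 1)
  set.seed(sub_seed(seed, "ratings"))
  truth <- sample.int(n_categories, n_items, replace = TRUE)
  tab <- matrix(0L, n_items, n_categories,
                dimnames = list(sprintf("item_%03d", seq_len(n_items)),
                                paste0("cat_", seq_len(n_categories) - 1L)))
  for (i in seq_len(n_items)) {
    agree <- runif(n_raters) < agreement_level
    votes <- integer(n_raters)
    votes[agree] <- truth[i]
    if (any(!agree)) {
      others <- setdiff(seq_len(n_categories), truth[i])
      votes[!agree] <- others[sample.int(length(others), sum(!agree),
                                         replace = TRUE)]
    }
    tab[i, ] <- tabulate(votes, nbins = n_categories)
  }
  attr(tab, "truth") <- truth - 1L
  tab
}

#' Simulate labelled bags of tile embeddings for multiple-instance learning
#'
#' Emulates tissue-microarray cores: negative bags contain only background
#' tiles from a standard Gaussian; positive bags contain
#' `round(signal_fraction * tiles_per_bag)` "signal" tiles whose mean is
#' shifted by `shift` along the first embedding axis. Per-tile signal flags
#' are returned so attention weights can be evaluated against ground truth.
#'
#' @param n_bags total bags; labels alternate 0/1 so classes are balanced.
#' @param tiles_per_bag instances per bag (>= 1).
#' @param signal_fraction fraction of signal tiles in positive bags, in (0, 1).
#' @param shift mean shift of signal tiles in within-tile standard deviations.
#' @param dim embedding dimensionality.
#' @param seed RNG seed.
#' @return list of bags; each is a list with `bag_id`, `label` (0/1),
#'   `instances` (`tiles_per_bag x dim` matrix) and `signal` (logical flags).
#' @export
simulate_bags <- function(n_bags, tiles_per_bag, signal_fraction, shift,
                          dim = 16L, seed = 1L) {
  if (tiles_per_bag < 1) stop("tiles_per_bag must be at least 1")
  stopifnot(n_bags >= 2, signal_fraction > 0, signal_fraction < 1, dim >= 1)
  set.seed(sub_seed(seed, "bags"))
  labels <- rep_len(c(0L, 1L), n_bags)
  n_signal <- as.integer(round(signal_fraction * tiles_per_bag))
  lapply(seq_len(n_bags), function(b) {
    inst <- matrix(rnorm(tiles_per_bag * dim), tiles_per_bag, dim)
    signal <- rep(FALSE, tiles_per_bag)
    if (labels[b] == 1L && n_signal > 0) {
      signal[seq_len(n_signal)] <- TRUE
      inst[signal, 1] <- inst[signal, 1] + shift
    }
    list(bag_id = sprintf("bag_%03d", b), label = labels[b],
         instances = inst, signal = signal)
  })
}

#' Simulate per-patient molecular signature scores
#'
#' Linked signatures are noisy linear functions of one HPC's clr coordinate,
#' calibrated so the population correlation equals the requested value;
#' unlinked signatures are independent standard-normal noise.
#'
#' @param patients patient table from [simulate_cohort()] (ids are reused).
#' @param truth ground truth from [simulate_cohort()] (supplies the true
#'   compositions whose clr coordinates drive linked signatures).
#' @param n_signatures total number of signature columns.
#' @param linked optional data frame with columns `signature` (column index,
#'   1-based), `hpc` (0-based component index) and `rho` (target correlation
#'   in (-1, 1)).
#' @param seed RNG seed.
#' @return numeric matrix, rows named by patient id, columns `sig_01`, ...
#' @export
simulate_signatures <- function(patients, truth, n_signatures,
                                linked = NULL, seed = 1L) {
  n <- nrow(patients)
  set.seed(sub_seed(seed, "signatures"))
  mat <- matrix(rnorm(n * n_signatures), n, n_signatures,
                dimnames = list(patients$patient_id,
                                if (n_signatures > 0)
                                  sprintf("sig_%02d", seq_len(n_signatures))))
  if (!is.null(linked) && nrow(linked)) {
    stopifnot(all(c("signature", "hpc", "rho") %in% names(linked)))
    C <- ncol(truth$patient_composition)
    clr_true <- clr_transform(truth$patient_composition)
    for (i in seq_len(nrow(linked))) {
      rho <- linked$rho[i]
      if (abs(rho) >= 1) stop("requested correlations must lie in (-1, 1)")
      hpc <- linked$hpc[i]
      if (hpc < 0 || hpc >= C) stop("unknown HPC index: ", hpc)
      z <- as.numeric(scale(clr_true[, hpc + 1L]))
      mat[, linked$signature[i]] <- rho * z + sqrt(1 - rho^2) * rnorm(n)
    }
  }
  mat
}
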