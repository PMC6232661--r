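#' Configuration of the synthetic questionnaire generator
#'
#' Collects every knob of the synthetic study: cohort size, questionnaire
#' noise, data-quality contamination, and the marginal targets the
#' ground-truth model is calibrated to.  The defaults emulate the hospital
#' study the package is built around: 408 returned questionnaires of which
#' 14 are straight-liners, an NSI 3-month prevalence of 27.9%, 55.4%
#' staffing judged sufficient (moderate or good), 75.8% reporting safe
#' work procedures available, 43.2% well motivated, and item noise placing
#' the per-scale Cronbach alphas in the high-0.7 to high-0.8 range.
#'
#' @param seed Integer seed driving all sampling.
#' @param n Number of respondents (default 408).
#' @param missing_rate Per-answer probability of a missing value
#'   (MCAR; applies to Likert items and direct answers alike).
#' @param straightliner_frac Fraction of respondents overwritten with a
#'   constant answer to every Likert item (default 14/408).
#' @param targets Named list of calibration targets: `nsi_yes`,
#'   `staffing_sufficient`, `procedures_available`, `motivation_good`.
#' @param effects Effect strengths (log-odds of the favourable child state
#'   per unit of mean parent favourability) for the three edge bundles:
#'   `l3` (organizational -> supervision), `l2` (supervision ->
#'   preconditions), `nsi` (preconditions -> outcome).  Zero effects make
#'   every child independent of its parents.
#' @param nsi_weights Relative weights of the four precondition parents in
#'   the outcome CPT; motivation is weighted highest, mirroring its
#'   leading role among the immediate NSI causes.
#' @param trait_sd Standard deviation of the respondent-level trait shared
#'   by all items of a scale.
#' @param item_sd Standard deviation of the per-item noise; the main dial
#'   for Cronbach alpha (larger = less reliable).
#' @param centre_spread Distance between the Likert item centres of
#'   adjacent latent states; the centres are `3 +/- centre_spread`
#'   for the outer states and 3 for the middle state.
#' @param management_prior Root prior of management commitment
#'   (poor/moderate/good).
#' @return A list of class `nsi_generator_config`.
#' @export
generator_config <- function(seed = 1L, n = 408L, missing_rate = 0.02,
                             straightliner_frac = 14 / 408,
                             targets = list(nsi_yes = 0.279,
                                            staffing_sufficient = 0.554,
                                            procedures_available = 0.758,
                                            motivation_good = 0.432),
                             effects = list(l3 = 1.6, l2 = 1.6, nsi = 3.0),
                             nsi_weights = c(fatigue = 1.2, teamwork = 0.8,
                                             physical_environment = 1.1,
                                             safety_motivation = 1.4),
                             trait_sd = 0.1, item_sd = 0.82,
                             centre_spread = 1.3,
                             management_prior = c(0.30, 0.40, 0.30)) {
  stopifnot(n >= 1, missing_rate >= 0, missing_rate <= 1,
            straightliner_frac >= 0, straightliner_frac <= 1,
            all(unlist(targets) >= 0), all(unlist(targets) <= 1),
            trait_sd >= 0, item_sd >= 0, centre_spread > 0,
            length(management_prior) == 3,
            abs(sum(management_prior) - 1) < 1e-9)
  structure(list(seed = as.integer(seed), n = as.integer(n),
                 missing_rate = missing_rate,
                 straightliner_frac = straightliner_frac,
                 targets = targets, effects = effects,
                 nsi_weights = nsi_weights, trait_sd = trait_sd,
                 item_sd = item_sd, centre_spread = centre_spread,
                 management_prior = management_prior),
            class = "nsi_generator_config")
}

# Favourability score of each state of a variable: 0 = worst for safety,
# 1 = best.  The favourable states are good management/staffing/attitude/
# training/teamwork/environment/motivation, procedures available, normal
# scheduling, low fatigue, and no NSI.
.favourability <- function(variable) {
  fav_first <- c("safe_procedures", "night_shifts", "working_hours", "fatigue")
  k <- length(variable$states)
  s <- seq(0, 1, length.out = k)
  if (variable$name %in% fav_first) rev(s) else s
}

# Ordered-logit CPT for one child: the probability of favourable states
# increases with the weighted mean favourability of the parent states.
.monotone_cpt <- function(structure, node, effect, shift = 0, weights = NULL) {
  v <- structure$variables[[node]]
  pa <- structure$parents[[node]]
  k <- length(v$states)
  fav <- .favourability(v)
  ord <- order(fav)                      # states from worst to best
  if (!length(pa)) stop("root nodes take explicit priors", call. = FALSE)
  w <- rep(1, length(pa))
  if (!is.null(weights)) {
    w <- weights[pa]
    if (anyNA(w)) stop("weights must cover all parents", call. = FALSE)
  }
  w <- w / sum(w)
  pf <- lapply(pa, function(p) .favourability(structure$variables[[p]]))
  conf <- parent_config_table(structure, node, labels = FALSE)
  f <- rowSums(vapply(seq_along(pa),
                      function(j) w[j] * pf[[j]][conf[, j]],
                      numeric(nrow(conf))))
  s <- effect * (f - 0.5) + shift
  m <- matrix(0, nrow(conf), k, dimnames = list(NULL, v$states))
  if (k == 2L) {
    pfav <- stats::plogis(1.0 + s)
    m[, ord[2L]] <- pfav
    m[, ord[1L]] <- 1 - pfav
  } else {
    q_best <- stats::plogis(-0.30 + s)   # P(best state)
    q_ge_mid <- stats::plogis(1.10 + s)  # P(middle or best)
    m[, ord[3L]] <- q_best
    m[, ord[2L]] <- q_ge_mid - q_best
    m[, ord[1L]] <- 1 - q_ge_mid
  }
  m
}

# Bisection on the additive logit shift of one node's CPT so that an exact
# marginal (computed by variable elimination) hits its target.
.calibrate_shift <- function(structure, cpts, node, state, target,
                             build, tol = 1e-4, lo = -8, hi = 8) {
  marg <- function(delta) {
    cpts[[node]] <- build(delta)
    bn_posterior(list(structure = structure, cpts = cpts), node)[[state]]
  }
  mlo <- marg(lo); mhi <- marg(hi)
  if ((mlo - target) * (mhi - target) > 0)
    stop("calibration target for '", node, "' (", target,
         ") is infeasible under the configured effects", call. = FALSE)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    mm <- marg(mid)
    if (abs(mm - target) < tol) return(mid)
    if ((mm - target) * (mlo - target) > 0) { lo <- mid; mlo <- mm }
    else hi <- mid
  }
  (lo + hi) / 2
}

#' Build the calibrated ground-truth model
#'
#' Constructs the layered HFACS network and fills every CPT with a
#' monotone ordered-logit table: the probability of the favourable child
#' state increases with the (weighted) mean favourability of the parent
#' states, scaled by the configured effect strengths.  Root priors are set
#' from the marginal targets (staffing sufficiency split equally between
#' its moderate and good states), and the safety-motivation and outcome
#' CPTs receive an additive logit shift tuned by bisection -- against
#' exact inference, no sampling -- until the model's motivation-good and
#' NSI-yes marginals hit their targets within 0.05 percentage points.
#'
#' @param config A [generator_config()].
#' @return A ground-truth model of class `hfacs_bn` with a `generator`
#'   element recording the configuration and the calibrated shifts.
#' @examples
#' truth <- make_ground_truth(generator_config(seed = 1))
#' bn_posterior(truth, "nsi")   # ~27.9% yes
#' @export
make_ground_truth <- function(config = generator_config()) {
  stopifnot(inherits(config, "nsi_generator_config"))
  structure_ <- hfacs_structure()
  nm <- names(structure_$variables)
  tg <- config$targets
  cpts <- stats::setNames(vector("list", length(nm)), nm)

  suff <- tg$staffing_sufficient
  cpts$management_commitment <-
    matrix(config$management_prior, 1, dimnames = list(NULL, c("poor", "moderate", "good")))
  cpts$staffing <-
    matrix(c(1 - suff, suff / 2, suff / 2), 1,
           dimnames = list(NULL, c("poor", "moderate", "good")))
  cpts$safe_procedures <-
    matrix(c(tg$procedures_available, 1 - tg$procedures_available), 1,
           dimnames = list(NULL, c("yes", "no")))

  lv <- vapply(structure_$variables, `[[`, integer(1), "level")
  for (v in nm[lv == 3L])
    cpts[[v]] <- .monotone_cpt(structure_, v, config$effects$l3)
  for (v in nm[lv == 2L])
    cpts[[v]] <- .monotone_cpt(structure_, v, config$effects$l2)
  cpts$nsi <- .monotone_cpt(structure_, "nsi", config$effects$nsi,
                            weights = config$nsi_weights)

  shift_mot <- .calibrate_shift(
    structure_, cpts, "safety_motivation", "good", tg$motivation_good,
    function(d) .monotone_cpt(structure_, "safety_motivation",
                              config$effects$l2, shift = d))
  cpts$safety_motivation <- .monotone_cpt(structure_, "safety_motivation",
                                          config$effects$l2, shift = shift_mot)
  shift_nsi <- .calibrate_shift(
    structure_, cpts, "nsi", "yes", tg$nsi_yes,
    function(d) .monotone_cpt(structure_, "nsi", config$effects$nsi,
                              shift = d, weights = config$nsi_weights))
  cpts$nsi <- .monotone_cpt(structure_, "nsi", config$effects$nsi,
                            shift = shift_nsi, weights = config$nsi_weights)

  model <- hfacs_bn(structure_, cpts)
  model$generator <- list(config = config,
                          shifts = c(safety_motivation = shift_mot,
                                     nsi = shift_nsi))
  model
}

# Ancestral sampling of latent states; returns an integer matrix n x nodes.
.ancestral_sample <- function(model, n) {
  structure_ <- model$structure
  nm <- names(structure_$variables)
  ord <- .topo_sort(structure_$parents)
  card <- .cards(structure_)
  S <- matrix(0L, n, length(nm), dimnames = list(NULL, nm))
  for (v in ord) {
    pa <- structure_$parents[[v]]
    conf <- if (length(pa)) .mixed_radix(S[, pa, drop = FALSE], card[pa])
            else rep(1L, n)
    P <- model$cpts[[v]][conf, , drop = FALSE]
    cs <- P
    for (j in seq_len(ncol(P))[-1L]) cs[, j] <- cs[, j - 1L] + cs[, j]
    u <- stats::runif(n)
    S[, v] <- 1L + rowSums(u > cs[, -ncol(cs), drop = FALSE])
  }
  S
}

.labels_from_states <- function(structure_, S) {
  out <- as.data.frame(S, stringsAsFactors = FALSE)
  for (v in colnames(S))
    out[[v]] <- structure_$variables[[v]]$states[S[, v]]
  out
}

#' Sample raw questionnaire records from a ground-truth model
#'
#' For each respondent the 12 latent states are drawn from the model's
#' joint distribution by ancestral sampling; the questionnaire instrument
#' is then emulated on top of them.  Likert items are drawn around a
#' state-specific centre (first/second/third state -> 2/3/4) plus a shared
#' respondent trait and per-item noise, rounded and clipped to 1-5; the
#' scheduling answers are drawn uniformly from the interval that defines
#' each state (hours capped at 84, night shifts at 16); binary answers are
#' emitted directly.  Missing answers are injected completely at random,
#' and the configured fraction of straight-liners is created by
#' overwriting every Likert item of those respondents with one constant
#' value.  All sampling is driven by `config$seed`, so a given
#' configuration always reproduces the same records byte for byte.
#'
#' @param truth Ground-truth model from [make_ground_truth()].
#' @param config A [generator_config()].
#' @return List with `records` (raw questionnaire data frame in the CSV
#'   dialect, including a `hospital` column that the model ignores),
#'   `latent` (the true state labels per respondent) and `straightliners`
#'   (row indices of the planted straight-liners).
#' @export
sample_respondents <- function(truth, config = generator_config()) {
  stopifnot(inherits(config, "nsi_generator_config"))
  truth <- .as_model(truth)
  structure_ <- truth$structure
  n <- config$n
  set.seed(config$seed)

  S <- .ancestral_sample(truth, n)
  items <- likert_item_columns(structure_$variables)
  rec <- data.frame(respondent_id = seq_len(n),
                    hospital = sample.int(5L, n, replace = TRUE))
  for (sc in names(items)) {
    centre <- 3 + config$centre_spread * (S[, sc] - 2L)
    trait <- stats::rnorm(n, 0, config$trait_sd)
    for (col in items[[sc]]) {
      x <- round(centre + trait + stats::rnorm(n, 0, config$item_sd))
      rec[[col]] <- pmin(5L, pmax(1L, as.integer(x)))
    }
  }
  nights_lo <- c(0L, 9L, 12L); nights_hi <- c(8L, 11L, 16L)
  hours_lo <- c(30L, 45L, 56L); hours_hi <- c(44L, 55L, 84L)
  k <- S[, "night_shifts"]
  rec$night_shifts <- nights_lo[k] +
    floor(stats::runif(n) * (nights_hi[k] - nights_lo[k] + 1L))
  k <- S[, "working_hours"]
  rec$working_hours <- hours_lo[k] +
    floor(stats::runif(n) * (hours_hi[k] - hours_lo[k] + 1L))
  rec$safe_procedures <- structure_$variables$safe_procedures$states[S[, "safe_procedures"]]
  rec$nsi <- structure_$variables$nsi$states[S[, "nsi"]]

  answer_cols <- c(unlist(items, use.names = FALSE),
                   "night_shifts", "working_hours", "safe_procedures", "nsi")
  if (config$missing_rate > 0) {
    for (col in answer_cols) {
      drop <- stats::runif(n) < config$missing_rate
      rec[[col]][drop] <- NA
    }
  }
  n_sl <- round(config$straightliner_frac * n)
  sl <- if (n_sl > 0) sort(sample.int(n, n_sl)) else integer(0)
  if (n_sl > 0) {
    const <- sample.int(5L, n_sl, replace = TRUE)
    for (col in unlist(items, use.names = FALSE))
      rec[[col]][sl] <- const
  }
  list(records = rec, latent = .labels_from_states(structure_, S),
       straightliners = sl)
}

#' Generate a complete synthetic study
#'
#' The full fixture pipeline: build the calibrated ground truth, sample
#' raw questionnaire records, preprocess them (straight-liner filter,
#' scale scoring, discretization) and split the retained records into
#' training and test sets (343/50 at the study scale, proportional below
#' it; see [split_train_test()]).
#'
#' @param config A [generator_config()].
#' @return List with `train`, `test`, `unused` (discretized data frames),
#'   `truth` (the generating `hfacs_bn`), `raw` (the sampled records),
#'   `latent` (true states), `preprocess` (the `nsi_preprocess` report)
#'   and `sizes`.
#' @examples
#' study <- make_study(generator_config(seed = 7))
#' nrow(study$train); nrow(study$test)   # 343, 50
#' @export
make_study <- function(config = generator_config()) {
  truth <- make_ground_truth(config)
  resp <- sample_respondents(truth, config)
  prep <- preprocess_questionnaire(resp$records, truth$structure$variables)
  split <- split_train_test(prep$data, seed = config$seed)
  list(train = split$train, test = split$test, unused = split$unused,
       truth = truth, raw = resp$records, latent = resp$latent,
       preprocess = prep, sizes = split$sizes)
}
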