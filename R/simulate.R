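#' Default potency-factor specifications
#'
#' The four surrogate potency factors scored by the matrix, with their
#' measurement units, panel means and target coefficients of variation
#' (CV, as a fraction). The CVs are the between-donor heterogeneities
#' observed on an 8-donor MSC panel: IDO1 47.3%, M-CSF 25.8%, CD63 20.5%,
#' CCL2 60.5%. The means are representative assay scales (per-donor raw
#' values are not published), fixed once for all simulations.
#'
#' @return A data frame with columns `factor_name`, `mean`, `cv`,
#'   `family`, `unit`.
#' @export
#' @examples
#' default_factor_specs()
default_factor_specs <- function() {
  data.frame(
    factor_name = c("IDO1", "MCSF", "CD63", "CCL2"),
    mean        = c(50, 1000, 25, 2500),
    cv          = c(0.473, 0.258, 0.205, 0.605),
    family      = "lognormal",
    unit        = c("% IDO1+ cells", "pg/mL", "ng/mL", "pg/mL"),
    stringsAsFactors = FALSE
  )
}

#' Assemble and validate a simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators into one
#' validated list, mirroring the structure the generators consume.
#'
#' @param seed Integer seed applied before each generator call.
#' @param n_donors Number of MSC donors in the simulated panel.
#' @param factor_specs Data frame as [default_factor_specs()].
#' @param cfse_spec List with `n_events`, `gen0_center` (undivided-peak
#'   fluorescence, arbitrary units), `peak_spread` (SD in log10
#'   fluorescence), `generation_probs` (probabilities over generations
#'   0..G, summing to 1).
#' @param dose_spec List with `doses` (MSC cell counts), `top`, `bottom`,
#'   `ic50`, `hill`, `noise_sd`.
#' @param pair_spec List with `n_pairs`, `rho`, `means`, `sds`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_donors = 8L,
                       factor_specs = default_factor_specs(),
                       cfse_spec = list(n_events = 10000L, gen0_center = 1e4,
                                        peak_spread = 0.05,
                                        generation_probs = c(0.15, 0.1, 0.15,
                                                             0.2, 0.2, 0.15,
                                                             0.05)),
                       dose_spec = list(doses = 10^seq(3, 5, length.out = 8),
                                        top = 1, bottom = 0, ic50 = 1e4,
                                        hill = 1, noise_sd = 0.05),
                       pair_spec = list(n_pairs = 10L, rho = -0.9,
                                        means = c(50, 2), sds = c(20, 0.4))) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (n_donors < 1) stop("n_donors must be >= 1", call. = FALSE)
  validate_factor_specs(factor_specs)
  validate_generation_probs(cfse_spec$generation_probs)
  if (cfse_spec$n_events <= 0) stop("n_events must be > 0", call. = FALSE)
  if (any(dose_spec$doses <= 0)) stop("doses must be > 0", call. = FALSE)
  if (dose_spec$top <= dose_spec$bottom)
    stop("top must exceed bottom", call. = FALSE)
  if (abs(pair_spec$rho) > 1) stop("|rho| must be <= 1", call. = FALSE)
  structure(list(seed = as.integer(seed), n_donors = as.integer(n_donors),
                 factor_specs = factor_specs, cfse_spec = cfse_spec,
                 dose_spec = dose_spec, pair_spec = pair_spec),
            class = "sim_config")
}

validate_factor_specs <- function(specs) {
  req <- c("factor_name", "mean", "cv")
  if (!all(req %in% names(specs)))
    stop("factor_specs needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(specs$cv < 0)) stop("CV must be >= 0", call. = FALSE)
  if (any(specs$mean <= 0)) stop("factor means must be > 0", call. = FALSE)
  invisible(specs)
}

validate_generation_probs <- function(p) {
  if (any(p < 0)) stop("generation probabilities must be >= 0", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9)
    stop("generation probabilities must sum to 1", call. = FALSE)
  invisible(p)
}

#' Simulate a donor panel of potency-factor measurements
#'
#' Draws one measurement per donor per factor. The default family is
#' lognormal (assay concentrations are nonnegative and right-skewed),
#' moment-matched so the distribution's true mean and CV equal the spec:
#' with target CV `c`, the log-scale variance is `log(1 + c^2)` and the
#' log-scale mean is `log(mean) - log(1 + c^2)/2`. `family = "normal"`
#' draws `N(mean, (cv * mean)^2)` instead (may emit negative values; no
#' clipping is applied). A CV of 0 yields the mean exactly.
#'
#' @param n_donors Number of donors (rows).
#' @param factor_specs Data frame with columns `factor_name`, `mean`,
#'   `cv` and optionally `family`; see [default_factor_specs()].
#' @param seed Optional integer seed set before drawing.
#' @param donor_ids Optional character vector of donor labels.
#' @return A data frame (the donor panel) with `donor_id` plus one column
#'   per factor.
#' @export
#' @examples
#' simulate_donor_panel(8, seed = 1)
simulate_donor_panel <- function(n_donors = 8L,
                                 factor_specs = default_factor_specs(),
                                 seed = NULL, donor_ids = NULL) {
  if (n_donors < 1) stop("n_donors must be >= 1", call. = FALSE)
  validate_factor_specs(factor_specs)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(donor_ids)) donor_ids <- sprintf("D%03d", seq_len(n_donors))
  stopifnot(length(donor_ids) == n_donors, !anyDuplicated(donor_ids))
  fam <- if ("family" %in% names(factor_specs)) factor_specs$family
         else rep("lognormal", nrow(factor_specs))
  panel <- data.frame(donor_id = donor_ids, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(factor_specs))) {
    m <- factor_specs$mean[i]; cv <- factor_specs$cv[i]
    panel[[factor_specs$factor_name[i]]] <-
      if (cv == 0) {
        rep(m, n_donors)
      } else if (fam[i] == "lognormal") {
        sdlog <- sqrt(log1p(cv^2))
        stats::rlnorm(n_donors, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
      } else if (fam[i] == "normal") {
        stats::rnorm(n_donors, mean = m, sd = cv * m)
      } else {
        stop("unknown distribution family: ", fam[i], call. = FALSE)
      }
  }
  panel
}

#' Simulate CFSE dye-dilution events
#'
#' Each cell division halves CFSE intensity, so generation g peaks at
#' `gen0_center / 2^g`. Events draw a generation from
#' `generation_probs`, then a fluorescence from a lognormal centred on
#' the generation peak with the stated spread in log10 units. The true
#' generation is retained in `true_generation`; analysis functions must
#' ignore it.
#'
#' @param n_events Number of cells (rows).
#' @param gen0_center Undivided-peak fluorescence, arbitrary units.
#' @param peak_spread SD of log10 fluorescence about each peak centre.
#' @param generation_probs Probabilities over generations `0..G`
#'   (nonnegative, summing to 1 within 1e-9).
#' @param condition Condition label stored with every event.
#' @param seed Optional integer seed.
#' @return Data frame with `condition`, `fluorescence`,
#'   `true_generation`.
#' @export
#' @examples
#' ev <- simulate_cfse_events(1000, generation_probs = c(0.5, 0.5), seed = 1)
#' table(ev$true_generation)
simulate_cfse_events <- function(n_events = 10000L, gen0_center = 1e4,
                                 peak_spread = 0.05,
                                 generation_probs = c(0.15, 0.1, 0.15, 0.2,
                                                      0.2, 0.15, 0.05),
                                 condition = "sample", seed = NULL) {
  if (n_events <= 0) stop("n_events must be > 0", call. = FALSE)
  if (gen0_center <= 0) stop("gen0_center must be > 0", call. = FALSE)
  validate_generation_probs(generation_probs)
  if (!is.null(seed)) set.seed(seed)
  gens <- 0:(length(generation_probs) - 1)
  g <- sample(gens, n_events, replace = TRUE, prob = generation_probs)
  f <- 10^stats::rnorm(n_events,
                       mean = log10(gen0_center) - g * log10(2),
                       sd = peak_spread)
  data.frame(condition = condition, fluorescence = f, true_generation = g,
             stringsAsFactors = FALSE)
}

#' Four-parameter logistic inhibition curve
#'
#' `bottom + (top - bottom) / (1 + (dose/ic50)^hill)`: the noiseless
#' response passes through `(top + bottom)/2` at `dose = ic50` and, for
#' `hill > 0`, decreases monotonically with dose.
#'
#' @param dose Dose (MSC cell count), positive.
#' @param top,bottom Response asymptotes at zero and infinite dose.
#' @param ic50 Dose at the curve midpoint (relative IC50).
#' @param hill Hill slope.
#' @return Response values.
#' @export
four_param_logistic <- function(dose, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)
}

#' Simulate a dose-response suppression series
#'
#' Normalized proliferation responses at the given MSC doses, following
#' the four-parameter logistic with additive Gaussian noise. With the
#' default `top = 1` the zero-dose response matches a control-normalized
#' replication index of 1.
#'
#' @param doses MSC cell counts (positive).
#' @param top,bottom,ic50,hill Curve parameters; `top > bottom`.
#' @param noise_sd SD of additive Gaussian noise on the response.
#' @param n_replicates Replicate measurements per dose.
#' @param seed Optional integer seed.
#' @return Data frame with `dose`, `response`, `replicate`.
#' @export
#' @examples
#' simulate_suppression_series(noise_sd = 0, n_replicates = 1)
simulate_suppression_series <- function(doses = 10^seq(3, 5, length.out = 8),
                                        top = 1, bottom = 0, ic50 = 1e4,
                                        hill = 1, noise_sd = 0.05,
                                        n_replicates = 3L, seed = NULL) {
  if (any(doses <= 0)) stop("doses must be > 0", call. = FALSE)
  if (top <= bottom) stop("top must exceed bottom", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  d <- rep(doses, each = n_replicates)
  mu <- four_param_logistic(d, top, bottom, ic50, hill)
  data.frame(dose = d,
             response = mu + stats::rnorm(length(d), 0, noise_sd),
             replicate = rep(seq_len(n_replicates), times = length(doses)))
}

#' Simulate surrogate/functional measurement pairs
#'
#' Draws pairs from a bivariate normal with the specified means, SDs and
#' Pearson correlation, on the analysis scale (no transform afterwards,
#' so the correlation target is exact in expectation). Negative draws are
#' possible and are not clipped; the generator targets correlation
#' structure, not marginal positivity.
#'
#' @param n_pairs Number of pairs.
#' @param rho Target Pearson correlation, in `[-1, 1]`.
#' @param means,sds Length-2 numeric: (surrogate, functional).
#' @param seed Optional integer seed.
#' @return Data frame with `surrogate`, `functional`.
#' @export
#' @examples
#' p <- simulate_correlated_pairs(1000, rho = -0.9, seed = 1)
#' cor(p$surrogate, p$functional)
simulate_correlated_pairs <- function(n_pairs = 10L, rho = -0.9,
                                      means = c(50, 2), sds = c(20, 0.4),
                                      seed = NULL) {
  if (abs(rho) > 1) stop("|rho| must be <= 1", call. = FALSE)
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  if (any(sds < 0)) stop("sds must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(n_pairs)
  z2 <- stats::rnorm(n_pairs)
  x <- means[1] + sds[1] * z1
  y <- means[2] + sds[2] * (rho * z1 + sqrt(1 - rho^2) * z2)
  data.frame(surrogate = x, functional = y)
}

#' Coefficient of variation
#'
#' Sample SD (n-1 denominator) divided by the mean; returned as a
#' fraction (multiply by 100 for percent).
#'
#' @param x Numeric values.
#' @return `sd(x)/mean(x)`.
#' @export
cv_fraction <- function(x) {
  m <- mean(x)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  stats::sd(x) / m
}
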