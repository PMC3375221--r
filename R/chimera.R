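REGIONS <- paste0("region", 1:5)

# Coerce the five region-origin columns to 0/1 numeric (reference species =
# 0 / "C", alternate = 1 / "P").
regionDesign <- function(tab) {
  for (r in REGIONS) {
    if (!r %in% names(tab)) stop("missing column: ", r)
    v <- tab[[r]]
    if (is.character(v) || is.factor(v)) {
      v <- as.character(v)
      if (!all(v %in% c("C", "P")))
        stop("region columns must be coded C/P or 0/1")
      v <- as.numeric(v == "P")
    }
    if (!all(v %in% c(0, 1))) stop("region columns must be coded C/P or 0/1")
    tab[[r]] <- v
  }
  tab
}

#' Fit the additive or pairwise-epistatic region model
#'
#' ML (not REML) linear mixed model of a growth-delay phenotype on the five
#' region-origin indicators of chimeric alleles, with a random intercept for
#' batch (96-well plate) to account for repeated measurement of the same
#' construct.  The intercept corresponds to the all-reference (all "C")
#' parent.  Parameters are counted as fixed effects + 2 variance components:
#' k = 8 additive, k = 18 with all ten pairwise interactions.
#'
#' @param tab data.frame with columns `region1`..`region5` (C/P or 0/1),
#'   `batch`, and the response column
#' @param interactions "none" (additive) or "pairwise" (adds all ten
#'   region-by-region products)
#' @param response name of the response column (default "delay_hours"; use
#'   the Z-scored column when days have been standardized)
#' @return an [LMMFit-class]
#' @export
fitRegionModel <- function(tab, interactions = c("none", "pairwise"),
                           response = "delay_hours") {
  interactions <- match.arg(interactions)
  if (!response %in% names(tab)) stop("missing response column: ", response)
  if (!"batch" %in% names(tab)) stop("missing batch column")
  tab <- regionDesign(tab)
  for (r in REGIONS)
    if (length(unique(tab[[r]])) < 2)
      stop("rank-deficient design: ", r,
           " is constant across all constructs")
  rhs <- if (interactions == "none")
    paste(REGIONS, collapse = " + ")
  else paste0("(", paste(REGIONS, collapse = " + "), ")^2")
  form <- stats::as.formula(paste(response, "~", rhs, "+ (1 | batch)"))
  fit <- suppressMessages(lme4::lmer(
    form, data = tab, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- lme4::VarCorr(fit)
  new("LMMFit",
      fixed_effects = fe, se = stats::setNames(se, names(fe)),
      p_values = stats::setNames(
        2 * stats::pnorm(-abs(fe / se)), names(fe)),
      batch_variance = as.numeric(vc$batch),
      residual_variance = attr(vc, "sc")^2,
      lnL = as.numeric(stats::logLik(fit)),
      n = nrow(tab), k = length(fe) + 2L,
      interactions = interactions, model = fit)
}

#' @rdname effectTable
#' @export
setMethod("effectTable", "LMMFit", function(x) {
  data.frame(term = names(x@fixed_effects),
             effect = unname(x@fixed_effects),
             se = unname(x@se),
             p_value = unname(x@p_values),
             row.names = NULL)
})

#' @export
setMethod("show", "LMMFit", function(object) {
  cat(sprintf("LMMFit (%s model, ML): n = %d, k = %d, lnL = %.3f\n",
              object@interactions, object@n, object@k, object@lnL))
  cat(sprintf("  batch variance %.4g, residual variance %.4g\n",
              object@batch_variance, object@residual_variance))
  print(effectTable(object), digits = 3)
})

#' Likelihood ratio test between nested region models
#'
#' Compares two ML [LMMFit-class]s of the same data (typically additive vs
#' pairwise-epistatic: 8 vs 18 counted parameters, 10 degrees of freedom).
#'
#' @param fit_null the smaller model
#' @param fit_alt the larger model
#' @return list with `stat` (2 dlnL), `df`, `p_value`
#' @export
lrtCompare <- function(fit_null, fit_alt) {
  stopifnot(is(fit_null, "LMMFit"), is(fit_alt, "LMMFit"))
  if (fit_null@n != fit_alt@n)
    stop("models were not fitted to the same data (n mismatch)")
  if (fit_alt@k <= fit_null@k)
    stop("fit_alt must be the larger (nesting) model")
  stat <- 2 * (fit_alt@lnL - fit_null@lnL)
  if (stat < -1e-6) stop("nesting violated: alternative lnL below null")
  df <- fit_alt@k - fit_null@k
  list(stat = stat, df = df, p_value = chiSquareSf(max(stat, 0), df))
}

#' Variance explained from a likelihood ratio statistic
#'
#' R^2 = 1 - exp(-LR/n) against the intercept-only null, the
#' likelihood-ratio based coefficient of determination.
#'
#' @param LR likelihood ratio statistic (>= 0) of a model against the
#'   intercept-only null
#' @param n sample size
#' @return value in [0, 1), monotone increasing in LR
#' @examples
#' varianceExplained(66 * log(4), 66)  # 0.75
#' @export
varianceExplained <- function(LR, n) {
  if (any(LR < 0)) stop("LR must be >= 0")
  if (any(n < 1)) stop("n must be >= 1")
  1 - exp(-LR / n)
}

#' Per-region percent contribution to the parent difference
#'
#' 100 |effect_i| / |total difference between the two full-length parents|.
#' Percents need not sum to 100: epistatic and nonsignificant terms absorb
#' the remainder.  The total is an explicit input rather than the sum of the
#' additive effects, since the two need not coincide.
#'
#' @param effects per-region additive coefficients
#' @param total_difference parent-allele difference in the same units
#' @return percent vector, same length/names as `effects`
#' @export
percentContribution <- function(effects, total_difference) {
  if (length(total_difference) != 1 || total_difference == 0)
    stop("total_difference must be a single nonzero value")
  100 * abs(effects) / abs(total_difference)
}

#' Permutation check of mixed-model p-value calibration
#'
#' Repeatedly permutes the construct labels (the whole block of region
#' indicators) across observations within each day, refits the region model,
#' and collects the parametric LRT p-value of the model against the
#' batch-only intercept null.  If the parametric p-values are accurate, the
#' permuted p-values are Uniform(0,1); the Kolmogorov-Smirnov distance to
#' uniformity is reported.  Deterministic given `seed`.
#'
#' @param tab phenotype table as for [fitRegionModel()]
#' @param interactions model flavour, "none" or "pairwise"
#' @param response response column name
#' @param nperm number of permutations, >= 100
#' @param seed RNG seed
#' @return list: `observed_p`, `permuted_p`, `ks_stat`, `ks_p`
#' @export
permutationPvalues <- function(tab, interactions = "none",
                               response = "delay_hours", nperm = 200,
                               seed = 1) {
  if (nperm < 100) stop("nperm must be >= 100")
  if (!"day" %in% names(tab)) stop("missing day column")
  tab <- regionDesign(tab)
  nullFit <- suppressMessages(lme4::lmer(
    stats::as.formula(paste(response, "~ 1 + (1 | batch)")), data = tab,
    REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  lnL0 <- as.numeric(stats::logLik(nullFit))
  pOf <- function(d) {
    f <- fitRegionModel(d, interactions, response)
    stat <- max(0, 2 * (f@lnL - lnL0))
    chiSquareSf(stat, f@k - 3L)   # free fixed effects beyond the intercept
  }
  observed <- pOf(tab)
  cols <- c("construct"[!is.na(match("construct", names(tab)))], REGIONS)
  permuted <- withSeed(deriveSeed(seed, 101L), {
    vapply(seq_len(nperm), function(b) {
      d <- tab
      for (dy in unique(d$day)) {
        i <- which(d$day == dy)
        d[i, cols] <- d[sample(i), cols]
      }
      pOf(d)
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(permuted, "punif"))
  list(observed_p = observed, permuted_p = permuted,
       ks_stat = unname(ks$statistic), ks_p = ks$p.value)
}
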