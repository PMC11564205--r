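#' Fit one regime-comparison model
#'
#' Gaussian identity-link fit of a [ModelSpec-class]: a plain linear model
#' when no random terms are given, otherwise a linear mixed model with
#' independent random intercepts, fitted by REML via [lmerTest::lmer()] so
#' that fixed-effect p-values use Satterthwaite degrees of freedom (the same
#' stack behavioural analyses conventionally report). A singular fit (a
#' random term estimated at zero variance) is recorded as a message but the
#' fit is retained — the fixed-effect estimates then coincide with the
#' corresponding OLS fit.
#'
#' @param spec a [ModelSpec-class].
#' @return `list(fit, coefficients, varcomp, formula, messages)`;
#'   `coefficients` has columns `term, estimate, se, df, statistic, p_value`.
#' @examples
#' d <- data.frame(y = c(1, 2, 3, 5, 6, 7),
#'                 g = rep(c("a", "b"), each = 3))
#' fitModel(ModelSpec("y", "g", character(), d))$coefficients
#' @export
fitModel <- function(spec) {
  stopifnot(is(spec, "ModelSpec"))
  dat <- spec@data
  for (v in spec@random) {
    dat[[v]] <- factor(dat[[v]])
    if (nlevels(dat[[v]]) < 2L)
      stop("random grouping factor '", v, "' has fewer than 2 levels")
  }
  rhs <- paste(spec@fixed, collapse = " + ")
  msgs <- character()
  if (length(spec@random)) {
    rhs <- paste(c(rhs, sprintf("(1 | %s)", spec@random)), collapse = " + ")
    form <- as.formula(paste(spec@response, "~", rhs))
    fit <- withCallingHandlers(
      suppressMessages(lmerTest::lmer(form, data = dat, REML = TRUE)),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (lme4::isSingular(fit))
      msgs <- c(msgs, "singular fit: a random-effect variance is zero")
    cf <- coef(summary(fit))
    coefs <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                        se = cf[, "Std. Error"], df = cf[, "df"],
                        statistic = cf[, "t value"],
                        p_value = cf[, "Pr(>|t|)"],
                        stringsAsFactors = FALSE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    varcomp <- data.frame(group = vc$grp, variance = vc$vcov,
                          sd = vc$sdcor, stringsAsFactors = FALSE)
  } else {
    form <- as.formula(paste(spec@response, "~", rhs))
    fit <- lm(form, data = dat)
    cf <- coef(summary(fit))
    coefs <- data.frame(term = rownames(cf), estimate = cf[, "Estimate"],
                        se = cf[, "Std. Error"],
                        df = fit$df.residual,
                        statistic = cf[, "t value"],
                        p_value = cf[, "Pr(>|t|)"],
                        stringsAsFactors = FALSE)
    varcomp <- data.frame(group = "Residual",
                          variance = summary(fit)$sigma^2,
                          sd = summary(fit)$sigma, stringsAsFactors = FALSE)
  }
  rownames(coefs) <- NULL
  list(fit = fit, coefficients = coefs, varcomp = varcomp,
       formula = deparse(form), messages = msgs)
}

#' All pairwise contrasts for one factor
#'
#' Produces every pairwise fixed-effect contrast of `factor` (for the three
#' selection regimes: low-high, low-control, high-control) by refitting the
#' model with each comparison level as the reference — numerically identical
#' to linear contrasts on a single fit, and it inherits the fitting
#' machinery's standard errors and (for mixed fits) Satterthwaite p-values.
#'
#' @param spec a [ModelSpec-class] whose fixed terms include `factor`.
#' @param factor name of the factor to contrast (default `"regime"`).
#' @return data.frame with one row per unordered pair: `level1, level2,
#'   contrast ("level1 - level2" = mean(level1) - mean(level2)), estimate,
#'   se, df, statistic, p_value, reference_level`.
#' @export
allPairwiseContrasts <- function(spec, factor = "regime") {
  dat <- spec@data
  if (!factor %in% names(dat)) stop("factor '", factor, "' not in data")
  lv <- if (factor == "regime" && all(unique(dat[[factor]]) %in% regimeLevels))
    intersect(regimeLevels, unique(as.character(dat[[factor]]))) else
    unique(as.character(dat[[factor]]))
  if (factor == "regime" && !all(regimeLevels %in% lv) &&
      identical(sort(regimeLevels), sort(union(lv, regimeLevels))))
    stop("regime level(s) missing from data: ",
         paste(setdiff(regimeLevels, lv), collapse = ", "))
  if (length(lv) < 2L) stop("factor '", factor, "' needs >= 2 levels")

  out <- list()
  for (j in 2:length(lv)) for (i in 1:(j - 1)) {
    a <- lv[i]; b <- lv[j]                    # contrast a - b, ref = b
    d2 <- dat
    d2[[factor]] <- relevel(factor(d2[[factor]], levels = lv), ref = b)
    fit <- fitModel(ModelSpec(spec@response, spec@fixed, spec@random, d2))
    row <- fit$coefficients[fit$coefficients$term == paste0(factor, a), ,
                            drop = FALSE]
    if (nrow(row) != 1L)
      stop("could not locate coefficient for level '", a, "'")
    out[[length(out) + 1L]] <- data.frame(
      level1 = a, level2 = b, contrast = paste(a, "-", b),
      estimate = row$estimate, se = row$se, df = row$df,
      statistic = row$statistic, p_value = row$p_value,
      reference_level = b, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Prune non-significant interaction terms
#'
#' Where no interaction term reaches significance the interactions are
#' removed and the model refitted, so that main effects are reported from
#' the reduced fit; if any interaction is significant the full model is
#' kept. Significance is `p < alpha` (default 0.05); at the boundary
#' `alpha = 0` no term can be significant and the interactions are always
#' pruned.
#'
#' @param spec a [ModelSpec-class] whose fixed terms include at least one
#'   interaction (`"a*b"` or `"a:b"`).
#' @param alpha pruning threshold (default 0.05).
#' @return `list(spec, fit, pruned = <logical>, interaction_p = <numeric>)`
#'   where `fit` is the reduced fit when pruned, the full fit otherwise.
#' @export
pruneInteractions <- function(spec, alpha = 0.05) {
  hasInt <- grepl("[*:]", spec@fixed)
  if (!any(hasInt))
    stop("spec contains no interaction term")
  full <- fitModel(spec)
  ip <- full$coefficients[grepl(":", full$coefficients$term), "p_value"]
  if (!length(ip)) stop("no interaction coefficients were estimated")
  if (any(ip < alpha))
    return(list(spec = spec, fit = full, pruned = FALSE,
                interaction_p = ip))
  mains <- unique(unlist(strsplit(spec@fixed[hasInt], "[*:]")))
  fixed <- unique(c(trimws(mains), spec@fixed[!hasInt]))
  spec2 <- ModelSpec(spec@response, fixed, spec@random, spec@data)
  list(spec = spec2, fit = fitModel(spec2), pruned = TRUE,
       interaction_p = ip)
}

#' Run the full battery of regime-comparison analyses
#'
#' Fits the eight analyses of the study design, one per response: dispersal
#' propensity (fixed-effects only), the three movement metrics (random
#' intercepts for block/line/camera as appropriate), the two surface-affinity
#' analyses (block intercept), and the two morphometric analyses
#' (regime-by-sex interaction with pruning, line intercept; leg length
#' additionally adjusts for the body-size axis PC1). Missing input tables
#' skip their rows with a logged reason rather than failing the battery.
#'
#' @param bundle named list of tidy tables (any subset):
#'   \describe{
#'     \item{dispersal}{`line_id, regime, mean_dispersals`}
#'     \item{movement}{`replicate_id, regime, block_id, line_id, camera_id,
#'       path_rate_px_s, sinuosity_p<p> ..., edge_affinity`}
#'     \item{surface}{`population_id, regime, block_id, n_total,
#'       n_on_surface`}
#'     \item{surface_selection}{`population_id, parent_class, block_id,
#'       n_total, n_on_surface`}
#'     \item{morphology}{`individual_id, line_id, regime, sex, pc1,
#'       leg_len`}
#'   }
#' @param sinuosityP which rediscretization distance's sinuosity to model
#'   (default 10; the battery can be rerun with 20 as a robustness check).
#' @param alpha interaction-pruning threshold (default 0.05).
#' @return Named list with one element per analysis:
#'   `list(contrasts, formula, messages)` or `list(skipped = <reason>)`.
#' @export
runTable1Battery <- function(bundle, sinuosityP = 10, alpha = 0.05) {
  out <- list()
  skip <- function(reason) list(skipped = reason)
  contrastsOf <- function(spec, factor = "regime") {
    fit <- fitModel(spec)
    list(contrasts = allPairwiseContrasts(spec, factor),
         formula = fit$formula, messages = fit$messages)
  }

  # dispersal propensity: line means, fixed regime effect only
  out$dispersal <- if (is.null(bundle$dispersal))
    skip("no dispersal table") else
    contrastsOf(ModelSpec("mean_dispersals", "regime", character(),
                          factorRegime(bundle$dispersal)))

  mv <- bundle$movement
  if (is.null(mv)) {
    out$path_length <- out$sinuosity <- out$edge_affinity <-
      skip("no movement table")
  } else {
    mv <- factorRegime(mv)
    out$path_length <- contrastsOf(
      ModelSpec("path_rate_px_s", "regime",
                c("block_id", "line_id", "camera_id"), mv))
    scol <- paste0("sinuosity_p", sinuosityP)
    out$sinuosity <- if (!scol %in% names(mv))
      skip(paste("no column", scol)) else
      contrastsOf(ModelSpec(scol, "regime", c("line_id", "camera_id"),
                            mv[!is.na(mv[[scol]]), , drop = FALSE]))
    out$edge_affinity <- contrastsOf(
      ModelSpec("edge_affinity", "regime", c("line_id", "camera_id"),
                mv[!is.na(mv$edge_affinity), , drop = FALSE]))
  }

  out$surface_affinity <- if (is.null(bundle$surface))
    skip("no surface table") else
    contrastsOf(ModelSpec("n_on_surface", "regime", "block_id",
                          factorRegime(bundle$surface)))

  out$surface_selection <- if (is.null(bundle$surface_selection)) {
    skip("no surface-selection table")
  } else {
    ss <- bundle$surface_selection
    ss$proportion <- ss$n_on_surface / ss$n_total
    ss$parent_class <- factor(ss$parent_class,
                              levels = c("not_surface", "surface"))
    contrastsOf(ModelSpec("proportion", "parent_class", "block_id", ss),
                factor = "parent_class")
  }

  mo <- bundle$morphology
  if (is.null(mo)) {
    out$body_size <- out$leg_length <- skip("no morphology table")
  } else {
    mo <- factorRegime(mo)
    pr <- pruneInteractions(ModelSpec("pc1", "regime*sex", "line_id", mo),
                            alpha = alpha)
    out$body_size <- list(
      contrasts = allPairwiseContrasts(pr$spec),
      formula = pr$fit$formula, messages = pr$fit$messages,
      interaction_pruned = pr$pruned, interaction_p = pr$interaction_p)
    ml <- mo[!is.na(mo$leg_len), , drop = FALSE]
    pr2 <- pruneInteractions(
      ModelSpec("leg_len", c("regime*sex", "pc1"), "line_id", ml),
      alpha = alpha)
    out$leg_length <- list(
      contrasts = allPairwiseContrasts(pr2$spec),
      formula = pr2$fit$formula, messages = pr2$fit$messages,
      interaction_pruned = pr2$pruned, interaction_p = pr2$interaction_p)
  }
  out
}

# order regime as low/high/control so pairwise contrasts print in the
# conventional order (low-high, low-control, high-control)
factorRegime <- function(d) {
  d$regime <- factor(as.character(d$regime),
                     levels = intersect(regimeLevels,
                                        unique(as.character(d$regime))))
  d
}

#' Serialize a battery report to a tidy coefficients table
#'
#' @param battery result of [runTable1Battery()].
#' @return data.frame with columns `analysis, contrast, estimate, se, df,
#'   statistic, p_value` (skipped analyses omitted).
#' @export
batteryTable <- function(battery) {
  rows <- lapply(names(battery), function(nm) {
    b <- battery[[nm]]
    if (!is.null(b$skipped)) return(NULL)
    cbind(analysis = nm,
          b$contrasts[, c("contrast", "estimate", "se", "df",
                          "statistic", "p_value")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
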