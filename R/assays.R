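#' Score a dispersal assay from phenotype-class tallies
#'
#' Each individual gets three standardized opportunities to emigrate from a
#' habitat patch; a line's dispersal propensity is the mean number of
#' realised dispersals per individual, in `[0, 3]`.
#'
#' @param counts tally of individuals by number of dispersals: a numeric
#'   vector of length 4 (classes 0..3, optionally named `"0".."3"`).
#' @param n number of assayed individuals; must equal `sum(counts)`.
#' @return Mean dispersals per individual.
#' @examples
#' scoreDispersal(c(`0` = 50, `1` = 25, `2` = 25, `3` = 100), 200)  # 1.875
#' @export
scoreDispersal <- function(counts, n = sum(counts)) {
  if (length(counts) != 4L)
    stop("counts must tally the four classes 0, 1, 2, 3 dispersals")
  if (!is.null(names(counts))) counts <- counts[as.character(0:3)]
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and complete")
  if (sum(counts) != n)
    stop(sprintf("inconsistent tally: sum(counts) = %d but n = %d",
                 sum(counts), n))
  if (n <= 0) stop("n must be positive")
  sum((0:3) * counts) / n
}

#' Classify a dispersal phenotype
#'
#' Individuals dispersing on all three opportunities display the dispersive
#' phenotype; those dispersing on none display the not-dispersive phenotype;
#' everything in between is intermediate (discarded during truncation
#' selection).
#'
#' @param k integer vector, dispersals out of three opportunities.
#' @return Character vector in `{"dispersive", "not_dispersive",
#'   "intermediate"}`.
#' @examples
#' classifyPhenotype(0:3)
#' @export
classifyPhenotype <- function(k) {
  if (any(!k %in% 0:3))
    stop("dispersal count must be an integer in 0..3")
  ifelse(k == 3, "dispersive",
         ifelse(k == 0, "not_dispersive", "intermediate"))
}

#' Tally per-individual dispersal counts into assay results
#'
#' Convenience for long-format input: counts dispersals per line and returns
#' the tidy per-line table with class tallies and the mean score.
#'
#' @param individuals data.frame with columns `line_id`, `regime`,
#'   `dispersals` (0..3).
#' @return data.frame with one row per line: `line_id, regime, n, c0..c3,
#'   mean_dispersals`.
#' @export
tallyDispersal <- function(individuals) {
  stopifnot(all(c("line_id", "regime", "dispersals") %in% names(individuals)))
  out <- do.call(rbind, lapply(split(individuals, individuals$line_id),
                               function(d) {
    cnt <- vapply(0:3, function(k) sum(d$dispersals == k), integer(1))
    data.frame(line_id = d$line_id[1], regime = d$regime[1],
               n = nrow(d), c0 = cnt[1], c1 = cnt[2], c2 = cnt[3],
               c3 = cnt[4],
               mean_dispersals = scoreDispersal(cnt, nrow(d)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Response to a single generation of selection on surface affinity
#'
#' Compares surface-affinity proportions between offspring of parents
#' collected on the habitat surface and offspring of parents collected below
#' it. Returns the class means and their difference, plus the fixed-effect
#' contrast from the model `proportion ~ parent class (+ block random
#' intercept when a block column with >= 2 levels is present)`.
#'
#' Surface counts are treated as stated minima (individuals can be obscured
#' by the substrate); no undercount correction is applied, and the returned
#' table carries the raw counts so the caveat travels with the data.
#'
#' @param offspringOfSurface,offspringOfNotSurface data.frames of replicate
#'   assays with columns `n_total`, `n_on_surface`, optionally `block_id`.
#' @return `list(means, difference, contrast, model)` where `contrast` is a
#'   one-row data.frame (estimate, se, p for surface minus not-surface).
#' @export
surfaceSelectionResponse <- function(offspringOfSurface,
                                     offspringOfNotSurface) {
  if (!nrow(offspringOfSurface) || !nrow(offspringOfNotSurface))
    stop("both parent classes need at least one replicate assay")
  mk <- function(d, cls) {
    stopifnot(all(c("n_total", "n_on_surface") %in% names(d)))
    if (any(d$n_on_surface < 0 | d$n_on_surface > d$n_total))
      stop("n_on_surface must lie in [0, n_total]")
    data.frame(parent_class = cls,
               proportion = d$n_on_surface / d$n_total,
               block_id = if ("block_id" %in% names(d))
                 as.character(d$block_id) else "1",
               stringsAsFactors = FALSE)
  }
  dat <- rbind(mk(offspringOfSurface, "surface"),
               mk(offspringOfNotSurface, "not_surface"))
  dat$parent_class <- factor(dat$parent_class,
                             levels = c("not_surface", "surface"))
  means <- tapply(dat$proportion, dat$parent_class, mean)

  random <- if (length(unique(dat$block_id)) > 1L) "block_id" else character()
  spec <- ModelSpec("proportion", "parent_class", random, dat)
  fit <- fitModel(spec)
  row <- fit$coefficients[fit$coefficients$term == "parent_classsurface", ,
                          drop = FALSE]
  list(means = means,
       difference = unname(means["surface"] - means["not_surface"]),
       contrast = data.frame(term = "surface - not_surface",
                             estimate = row$estimate, se = row$se,
                             p_value = row$p_value),
       model = fit)
}
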