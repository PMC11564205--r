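#' Repeatability of morphometric measurements
#'
#' Spearman's rank correlation (midranks for ties) between first and second
#' measurements of the same structures on the same individuals. Traits whose
#' repeatability falls below the retention threshold are flagged for
#' exclusion from downstream condensation; the default threshold of 0.9 is a
#' configurable package choice — it separates "highly repeatable" traits
#' from, e.g., a first tarsus segment remeasuring at rho ~ 0.73.
#'
#' @param first,second data.frames with an `individual_id` column plus one
#'   column per trait; each individual in `second` must appear in `first`.
#' @param traits trait columns to screen; default: all shared non-id columns.
#' @param threshold retention threshold on rho (default 0.9).
#' @return `list(table = <data.frame trait/rho/n/retained>,
#'   retained = <character>)`.
#' @examples
#' a <- data.frame(individual_id = 1:5, elytron_len = c(1, 2, 3, 4, 5))
#' b <- data.frame(individual_id = 1:5, elytron_len = c(1, 3, 2, 4, 5))
#' repeatability(a, b)$table$rho  # 1 - 6*2/(5*24) = 0.9
#' @export
repeatability <- function(first, second, traits = NULL, threshold = 0.9) {
  stopifnot("individual_id" %in% names(first),
            "individual_id" %in% names(second))
  unpaired <- setdiff(second$individual_id, first$individual_id)
  if (length(unpaired))
    stop("individuals in the repeat set lack a first measurement: ",
         paste(unpaired, collapse = ", "))
  if (is.null(traits))
    traits <- setdiff(intersect(names(first), names(second)),
                      c("individual_id", "line_id", "regime", "sex",
                        "repeat_index"))
  idx <- match(second$individual_id, first$individual_id)
  tab <- do.call(rbind, lapply(traits, function(tr) {
    x <- first[[tr]][idx]; y <- second[[tr]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 5L)
      stop("need at least 5 paired measurements for trait '", tr, "'")
    rho <- cor(x[ok], y[ok], method = "spearman")
    data.frame(trait = tr, rho = rho, n = sum(ok),
               retained = rho >= threshold - 1e-12,  # fp-safe boundary
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(table = tab, retained = tab$trait[tab$retained])
}

#' Keep only records with every listed trait measured
#'
#' Factor condensation cannot use records with missing measurements, so the
#' analysis takes forward only individuals for which all retained traits
#' were quantified (e.g. femur length is often unmeasurable when thorax
#' tissue obscures the joint).
#'
#' @param records morphometrics data.frame.
#' @param traits character vector of trait columns that must be non-missing.
#' @return The filtered data.frame, with attribute `"n_dropped"`.
#' @export
completeCases <- function(records, traits) {
  if (!length(traits)) stop("trait list must be non-empty")
  keep <- complete.cases(records[, traits, drop = FALSE])
  out <- records[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Condense correlated traits into a body-size axis (correlation-matrix PCA)
#'
#' Eigen-decomposition of the trait correlation matrix on complete cases.
#' Scores are the standardized traits projected on the eigenvectors, and the
#' variance fraction of each component is its eigenvalue divided by the
#' number of traits. PC1's sign is fixed deterministically: if the sum of
#' its loadings is negative, PC1 (loadings and scores) is flipped so that
#' larger scores mean larger bodies — eigenvectors are otherwise only
#' defined up to sign, and all-negative loadings invert interpretation.
#'
#' @param records morphometrics data.frame (complete for `traits`).
#' @param traits trait columns to condense; defaults to the four retained
#'   linear measurements.
#' @return `list(pc1 = <scores>, scores = <matrix>, loadings = <matrix>,
#'   variance_fractions = <numeric>, eigenvalues = <numeric>,
#'   n_complete = <int>)`.
#' @export
sizePCA <- function(records,
                    traits = c("elytron_len", "femur_len", "femur_width",
                               "tibia_len")) {
  if (length(traits) < 2L) stop("need at least 2 traits")
  X <- as.matrix(records[, traits, drop = FALSE])
  if (anyNA(X))
    stop("PCA requires complete cases; run completeCases() first")
  if (nrow(X) <= length(traits))
    stop("need more complete cases than traits")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("zero-variance trait: ", paste(traits[sds == 0], collapse = ", "))
  Z <- scale(X)
  eg <- eigen(cor(X), symmetric = TRUE)
  load <- eg$vectors
  dimnames(load) <- list(traits, paste0("PC", seq_along(traits)))
  if (sum(load[, 1]) < 0) load[, 1] <- -load[, 1]
  scores <- Z %*% load
  list(pc1 = scores[, 1], scores = scores, loadings = load,
       variance_fractions = eg$values / length(traits),
       eigenvalues = eg$values, n_complete = nrow(X))
}

#' Leg length (femur + tibia)
#'
#' The stride-relevant linear extent of the rear leg: femur length plus
#' tibia length, in millimetres. Undefined (`NA`) when either part is
#' missing.
#'
#' @param records morphometrics data.frame with `femur_len` and `tibia_len`
#'   columns (or a single record as a one-row data.frame/list).
#' @return Numeric vector of leg lengths, `NA` where a part is missing.
#' @examples
#' legLength(data.frame(femur_len = 1.0, tibia_len = 1.2))  # 2.2
#' @export
legLength <- function(records) {
  stopifnot(all(c("femur_len", "tibia_len") %in% names(records)))
  records$femur_len + records$tibia_len
}
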