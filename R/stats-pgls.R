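#' Phylogenetic generalized least squares on arcsine-square-root proportions
#'
#' Regresses one proportion on another across the tips of a dated tree,
#' with both variables transformed by \eqn{\arcsin\sqrt{p}} (the standard
#' variance-stabilising transform for proportions bounded at the
#' extremes) and Brownian-motion error covariance from the tree,
#' off-diagonal elements scaled by Pagel's lambda. With `lambda = 0` the
#' fit reduces exactly to ordinary least squares on the transformed
#' values; `lambda = "ml"` profiles the likelihood over `[0, 1]`.
#'
#' @param response,predictor named numeric vectors of proportions in
#'   `[0, 1]`, one value per tree tip.
#' @param tree a [dated_tree()] covering all tips.
#' @param lambda `"ml"` or a fixed value in `[0, 1]`.
#' @return list with `slope`, `intercept`, `statistic` (t for the slope),
#'   `df`, `p_value`, `lambda`, `sigma2`, `logLik`.
#' @export
pgls_arcsine <- function(response, predictor, tree, lambda = "ml") {
  if (any(response < 0 | response > 1) || any(predictor < 0 | predictor > 1)) {
    stop("proportions must lie in [0, 1]")
  }
  phy <- tree$phylo
  tips <- phy$tip.label
  if (!all(tips %in% names(response)) || !all(tips %in% names(predictor))) {
    stop("response and predictor must be named by the tree tips")
  }
  y <- as.numeric(asin(sqrt(response[tips])))
  x <- as.numeric(asin(sqrt(predictor[tips])))
  n <- length(tips)
  V0 <- ape::vcv(phy)
  Vlam <- function(lam) {
    V <- V0 * lam
    diag(V) <- diag(V0)
    V
  }
  fit <- function(lam) {
    V <- Vlam(lam)
    Vi <- tryCatch(solve(V), error = function(e) {
      stop("singular phylogenetic covariance matrix")
    })
    X <- cbind(1, x)
    XtVi <- crossprod(X, Vi)
    beta_cov <- solve(XtVi %*% X)
    beta <- beta_cov %*% (XtVi %*% y)
    resid <- y - X %*% beta
    rss <- drop(crossprod(resid, Vi %*% resid))
    sigma2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) +
                    determinant(V, logarithm = TRUE)$modulus + n)
    list(beta = drop(beta), beta_cov = beta_cov, sigma2 = sigma2,
         logLik = drop(ll), rss = rss)
  }
  if (identical(lambda, "ml")) {
    opt <- stats::optimize(function(l) fit(l)$logLik, c(0, 1), maximum = TRUE)
    # compare against the boundaries, optimize() can miss them
    cand <- c(0, opt$maximum, 1)
    lls <- vapply(cand, function(l) fit(l)$logLik, numeric(1L))
    lam_hat <- cand[which.max(lls)]
  } else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1) {
      stop("lambda must be 'ml' or a value in [0, 1]")
    }
    lam_hat <- lambda
  }
  f <- fit(lam_hat)
  df <- n - 2L
  se <- sqrt(f$beta_cov[2L, 2L] * f$rss / df)
  tstat <- f$beta[2L] / se
  list(slope = unname(f$beta[2L]), intercept = unname(f$beta[1L]),
       statistic = unname(tstat), df = df,
       p_value = unname(2 * stats::pt(-abs(tstat), df)),
       lambda = lam_hat, sigma2 = f$sigma2, logLik = f$logLik)
}

#' GC-amelioration trend of foreign transcripts
#'
#' For each foreign transcript, the GC deviation from its species
#' background (`delta = gc - background`) is related to the phylogenetic
#' breadth of its ortholog group, ordered `unique < sister < genus <
#' shared_outgroup`. When the donor composition is GC-richer than the
#' host background, amelioration shows up as a negative Spearman
#' correlation between breadth ordinal and signed deviation: recently
#' acquired (narrowly distributed) genes sit furthest from the host
#' background, while older, widely shared genes have drifted toward it.
#'
#' @param gc numeric vector of per-transcript GC fractions.
#' @param species species label per transcript.
#' @param class distribution class per transcript (`unique`, `sister`,
#'   `genus`, `shared_outgroup`; span suffixes are tolerated).
#' @param background named numeric vector of per-species background GC.
#' @return list with `deltas` (`data.frame` of per-transcript deviations
#'   and class ordinals), `per_class` (mean delta per species x class),
#'   `per_species` (`data.frame` of Spearman rho/p per species) and
#'   `overall` (Spearman over all transcripts).
#' @export
gc_trend <- function(gc, species, class, background) {
  ord_levels <- c("unique", "sister", "genus", "shared_outgroup")
  cls <- distribution_class(class)
  if (!all(cls %in% ord_levels)) {
    stop("unknown distribution class: ",
         paste(setdiff(unique(cls), ord_levels), collapse = ", "))
  }
  ordinal <- match(cls, ord_levels)
  delta <- gc - background[species]
  deltas <- data.frame(species = species, class = cls, ordinal = ordinal,
                       gc = gc, delta = unname(delta),
                       stringsAsFactors = FALSE)
  per_class <- tapply(deltas$delta, list(deltas$species, deltas$class), mean)
  per_class <- per_class[, intersect(ord_levels, colnames(per_class)),
                         drop = FALSE]
  one_trend <- function(d) {
    if (length(unique(d$ordinal)) < 2L) {
      return(c(rho = NA_real_, p_value = NA_real_))
    }
    s <- spearman_cor(d$ordinal, d$delta)
    c(rho = s$rho, p_value = s$p_value)
  }
  per_species <- do.call(rbind, lapply(split(deltas, deltas$species), one_trend))
  per_species <- data.frame(species = rownames(per_species), per_species,
                            row.names = NULL, stringsAsFactors = FALSE)
  overall <- one_trend(deltas)
  list(deltas = deltas, per_class = per_class,
       per_species = per_species,
       overall = list(rho = unname(overall["rho"]),
                      p_value = unname(overall["p_value"])))
}
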