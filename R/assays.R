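#' Relative gene expression by the comparative Ct method
#'
#' Per sample, `dCt = Ct_target - Ct_housekeeping` (technical replicates of
#' a gene within a sample are averaged first); per group,
#' `ddCt = mean(dCt_group) - mean(dCt_control)` and the fold change is
#' `2^-ddCt`, assuming doubling per cycle. The control group's fold is 1 by
#' construction. Samples missing the housekeeping gene are dropped with a
#' warning.
#'
#' @param table data.frame with columns `sample_id, group, gene, replicate,
#'   ct`.
#' @param housekeeping housekeeping gene name (default `"GAPDH"`).
#' @param control_group name of the reference group.
#' @return data.frame `(gene, group, n, delta_ct, ddct, fold)` with
#'   attribute `per_sample` (per-sample dCt and fold for error bars).
#' @export
relative_expression <- function(table, housekeeping = "GAPDH",
                                control_group) {
  req <- c("sample_id", "group", "gene", "replicate", "ct")
  if (!all(req %in% names(table))) {
    stop("Ct table must have columns: ", paste(req, collapse = ", "))
  }
  if (any(table$ct <= 0)) stop("Ct values must be positive")
  hk <- table[table$gene == housekeeping, ]
  if (!nrow(hk)) stop("housekeeping gene '", housekeeping, "' absent")
  hk_mean <- tapply(hk$ct, hk$sample_id, mean)
  tg <- table[table$gene != housekeeping, ]
  missing_hk <- setdiff(unique(tg$sample_id), names(hk_mean))
  if (length(missing_hk)) {
    warning("dropping sample(s) without housekeeping Ct: ",
            paste(missing_hk, collapse = ", "))
    tg <- tg[!tg$sample_id %in% missing_hk, ]
  }
  # technical replicates averaged within sample x gene
  agg <- stats::aggregate(ct ~ sample_id + group + gene, data = tg, FUN = mean)
  agg$delta_ct <- agg$ct - as.numeric(hk_mean[as.character(agg$sample_id)])
  if (!control_group %in% agg$group) {
    stop("control group '", control_group, "' absent for the target genes")
  }
  out <- list()
  for (g in unique(agg$gene)) {
    sub <- agg[agg$gene == g, ]
    ctrl <- sub$delta_ct[sub$group == control_group]
    if (!length(ctrl)) stop("control group missing for gene ", g)
    dct_ctrl <- mean(ctrl)
    for (gr in unique(sub$group)) {
      d <- sub$delta_ct[sub$group == gr]
      ddct <- mean(d) - dct_ctrl
      out[[length(out) + 1L]] <- data.frame(
        gene = g, group = gr, n = length(d),
        delta_ct = mean(d), ddct = ddct, fold = 2^(-ddct))
    }
  }
  res <- do.call(rbind, out)
  ctrl_mean <- tapply(agg$delta_ct[agg$group == control_group],
                      agg$gene[agg$group == control_group], mean)
  per_sample <- agg
  per_sample$fold <- 2^-(per_sample$delta_ct -
                           as.numeric(ctrl_mean[as.character(per_sample$gene)]))
  attr(res, "per_sample") <- per_sample
  res
}

.fourpl <- function(x, a, d, c, b) d + (a - d) / (1 + (x / c)^b)

#' Fit a four-parameter logistic (4PL) standard curve
#'
#' Least-squares fit of `y = d + (a - d) / (1 + (x/c)^b)` — `a` the
#' zero-concentration asymptote, `d` the saturating asymptote, `c` the
#' inflection concentration (EC50) and `b` the slope — as used for ELISA
#' standard curves read at 450 nm. Fitting uses Levenberg-Marquardt
#' (minpack.lm) with multi-start from heuristic initials (asymptotes from
#' the response extremes, `c` from the mid-response concentration) plus
#' seeded jitter restarts.
#'
#' @param concentrations standard concentrations (>= 5 distinct, > 0).
#' @param responses optical densities.
#' @param n_starts number of jittered restarts.
#' @param seed seed for the start jitter.
#' @return object of class `standard_curve`: `params` (a, d, c, b),
#'   `residuals`, `range` (fitted concentration range), `rss`.
#' @export
fit_4pl <- function(concentrations, responses, n_starts = 8, seed = 1) {
  x <- as.numeric(concentrations); y <- as.numeric(responses)
  if (length(unique(x)) < 5) stop("need >= 5 distinct concentrations")
  if (any(!is.finite(y))) stop("responses must be finite")
  if (any(x < 0)) stop("concentrations must be >= 0")
  ord <- order(x)
  xo <- x[ord]; yo <- y[ord]
  a0 <- yo[1]; d0 <- yo[length(yo)]
  mid <- (a0 + d0) / 2
  c0 <- xo[which.min(abs(yo - mid))]
  if (c0 <= 0) c0 <- stats::median(xo[xo > 0])
  starts <- list(c(a = a0, d = d0, c = c0, b = 1))
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = .GlobalEnv)
  }, add = TRUE)
  set.seed(seed)
  for (i in seq_len(n_starts - 1)) {
    starts[[i + 1]] <- c(a = a0 * stats::runif(1, 0.8, 1.2) +
                           stats::rnorm(1, 0, 0.01),
                         d = d0 * stats::runif(1, 0.8, 1.2),
                         c = c0 * exp(stats::rnorm(1, 0, 0.5)),
                         b = exp(stats::rnorm(1, 0, 0.4)))
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ d + (a - d) / (1 + (x / c)^b),
                        data = data.frame(x = x, y = y),
                        start = as.list(st),
                        lower = c(a = -Inf, d = -Inf, c = 1e-12, b = -50),
                        upper = c(a = Inf, d = Inf, c = Inf, b = 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("4PL fit failed to converge from any start; check that the ",
         "responses are monotone in concentration and span both asymptotes")
  }
  p <- stats::coef(best$fit)
  structure(list(params = p, residuals = stats::residuals(best$fit),
                 range = range(x), rss = best$rss),
            class = "standard_curve")
}

#' Predict response from a 4PL standard curve
#' @param curve a `standard_curve`. @param concentration x values.
#' @return predicted optical densities.
#' @export
predict_4pl <- function(curve, concentration) {
  p <- curve$params
  .fourpl(concentration, p["a"], p["d"], p["c"], p["b"])
}

#' Inverse prediction (concentration from optical density)
#'
#' Solves the 4PL for x: `x = c * ((a - d)/(y - d) - 1)^(1/b)`. Responses
#' at or beyond the asymptotes are out of range.
#'
#' @param curve a `standard_curve` from [fit_4pl()].
#' @param od optical density value(s).
#' @return estimated concentration(s).
#' @export
inverse_4pl <- function(curve, od) {
  p <- curve$params
  lo <- min(p["a"], p["d"]); hi <- max(p["a"], p["d"])
  if (any(od <= lo | od >= hi)) {
    stop(sprintf(paste0("optical density outside the curve's open range ",
                        "(%.4g, %.4g)"), lo, hi))
  }
  unname(p["c"] * ((p["a"] - p["d"]) / (od - p["d"]) - 1)^(1 / p["b"]))
}
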