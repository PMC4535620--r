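#' Gene-wise negative binomial dispersion estimation
#'
#' Method-of-moments dispersion on depth-normalized counts with shrinkage
#' toward a log-log mean--dispersion trend.  For each gene the raw
#' dispersion is `max(0, (s2 - mu) / mu^2)` where `mu` and `s2` are the
#' mean and variance of normalized counts pooled within condition groups
#' (so condition effects do not inflate the estimate).  The trend is a
#' linear regression of log raw dispersion on log mean over genes with
#' positive raw dispersion.  The final dispersion is the maximum of the
#' (optionally trend-blended) per-gene value and the trend itself: with
#' few replicates the moment estimator underestimates dispersion for
#' many genes, and flooring at the trend keeps the downstream Wald test
#' calibrated (the conservative sharing mode of the original NB DE
#' tools).
#'
#' This is a deliberately simple, fully specified NB variance model (no
#' Cox--Reid adjustment, no fold-change shrinkage, no independent
#' filtering).
#'
#' @param cm a [count_matrix()]; its sample sheet defines the replicate
#'   groups via `condition`.
#' @param factors size factors (default: median-of-ratios).
#' @param trend_weight weight of the trend in the log-scale blend with
#'   the raw value, applied before the trend floor (default 0, i.e.
#'   final = max(raw, trend)); genes with zero raw dispersion take the
#'   trend value.
#' @param alpha_floor lower bound used for the raw value in the
#'   combination (default 1e-8).
#' @return a `dispersion_fit` list with `alpha_raw`, `alpha_trend`,
#'   `alpha` (final), `base_mean` and the trend coefficients.
#' @export
estimate_dispersions <- function(cm, factors = NULL, trend_weight = 0,
                                 alpha_floor = 1e-8) {
  if (is.null(factors)) factors <- size_factors_median_of_ratios(cm)
  norm <- sweep(cm$counts, 2, factors[colnames(cm$counts)], "/")
  groups <- split(seq_len(ncol(norm)), cm$samples$condition)
  if (any(lengths(groups) < 2))
    stopf("dispersion estimation requires >= 2 replicates per group (offending: %s)",
          paste(names(groups)[lengths(groups) < 2], collapse = ", "))
  ## pooled within-group moments
  ss <- 0; df <- 0; mu_w <- 0
  for (idx in groups) {
    g <- norm[, idx, drop = FALSE]
    m <- rowMeans(g)
    ss <- ss + rowSums((g - m)^2)
    df <- df + (length(idx) - 1)
    mu_w <- mu_w + m * length(idx)
  }
  mu <- mu_w / ncol(norm)
  s2 <- ss / df
  raw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  pos <- raw > 0 & mu > 0
  if (sum(pos) >= 10) {
    fit <- lm(log(raw[pos]) ~ log(mu[pos]))
    beta <- coef(fit)
  } else {
    beta <- c(log(pmax(mean(raw), alpha_floor)), 0)
  }
  trend <- exp(beta[1] + beta[2] * log(pmax(mu, alpha_floor)))
  trend <- pmin(pmax(trend, alpha_floor), 10)
  blend <- exp(trend_weight * log(trend) +
               (1 - trend_weight) * log(pmax(raw, alpha_floor)))
  final <- pmax(blend, trend)
  final[raw == 0] <- trend[raw == 0]
  structure(list(alpha_raw = raw, alpha_trend = trend, alpha = final,
                 base_mean = mu, trend_coef = beta,
                 trend_weight = trend_weight), class = "dispersion_fit")
}

#' Negative binomial Wald test between two conditions
#'
#' Per gene: the log2 fold change of depth-normalized group means (a
#' small offset avoids infinities), a delta-method standard error from
#' the NB variance `mu + alpha * mu^2`, the Wald statistic `lfc / SE`
#' and a two-sided normal p-value.  Genes with zero counts in both
#' groups get `log2FC = 0`, `p = 1` and are flagged.
#'
#' @param cm a [count_matrix()].
#' @param group_a,group_b condition names (fold change of B over A).
#' @param factors size factors (default: median-of-ratios).
#' @param fit a `dispersion_fit`; computed when missing.
#' @param offset normalized-count offset added to each group mean before
#'   the ratio (default 0.5).
#' @return data.frame of class `de_result`: `gene`, `baseMean`,
#'   `log2FC`, `SE`, `stat`, `p`, `fdr`, `call`, `all_zero`.
#' @export
nb_wald_test <- function(cm, group_a, group_b, factors = NULL, fit = NULL,
                         offset = 0.5) {
  if (is.null(factors)) factors <- size_factors_median_of_ratios(cm)
  sa <- condition_samples(cm, group_a)
  sb <- condition_samples(cm, group_b)
  if (length(intersect(sa, sb))) stopf("groups must be disjoint")
  if (length(sa) < 2 || length(sb) < 2)
    stopf("each group needs >= 2 samples")
  if (is.null(fit)) {
    sub <- count_matrix(cm$counts[, c(sa, sb), drop = FALSE], cm$lengths,
                        cm$samples[cm$samples$sample %in% c(sa, sb), ,
                                   drop = FALSE])
    fit <- estimate_dispersions(sub, factors[c(sa, sb)])
  }
  alpha <- fit$alpha
  norm <- sweep(cm$counts, 2, factors[colnames(cm$counts)], "/")
  ma <- rowMeans(norm[, sa, drop = FALSE])
  mb <- rowMeans(norm[, sb, drop = FALSE])
  lfc <- log2((mb + offset) / (ma + offset))
  ## delta-method variance of log2 group means; normalized count K/f has
  ## variance q/f + alpha q^2 at true rate q
  v_group <- function(m, smp) {
    q <- m + offset
    f <- factors[smp]
    vs <- outer(q, 1 / f) + alpha * q^2
    rowSums(vs) / length(smp)^2 / (q^2) / log(2)^2
  }
  se <- sqrt(v_group(ma, sa) + v_group(mb, sb))
  stat <- lfc / se
  p <- 2 * pnorm(-abs(stat))
  all_zero <- ma == 0 & mb == 0
  lfc[all_zero] <- 0; stat[all_zero] <- 0; p[all_zero] <- 1
  res <- data.frame(gene = rownames(cm$counts),
                    baseMean = (ma + mb) / 2,
                    log2FC = lfc, SE = se, stat = stat, p = p,
                    fdr = bh_adjust(p), all_zero = all_zero,
                    stringsAsFactors = FALSE)
  res$call <- ifelse(res$fdr < 0.01, ifelse(res$log2FC > 0, "up", "down"),
                     "ns")
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  attr(res, "contrast") <- c(group_a, group_b)
  res
}

#' Benjamini--Hochberg step-up adjusted p-values
#'
#' Classic step-up: on p-values sorted increasingly,
#' `fdr(i) = min_{j >= i} p(j) * m / j`, mapped back to input order
#' (ties handled stably).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of BH-adjusted values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(adj, 1)[order(o)]
}

#' Partition differential calls at an FDR threshold
#'
#' @param res a `de_result` from [nb_wald_test()].
#' @param fdr_threshold significance threshold on BH-adjusted values
#'   (default 0.01).
#' @return list with `up` and `down` gene-id vectors and the refreshed
#'   result table.
#' @export
call_degs <- function(res, fdr_threshold = 0.01) {
  sig <- res$fdr < fdr_threshold
  res$call <- ifelse(sig, ifelse(res$log2FC > 0, "up", "down"), "ns")
  list(up = res$gene[sig & res$log2FC > 0],
       down = res$gene[sig & res$log2FC < 0],
       table = res)
}
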