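#' Cluster-based permutation test over electrodes
#'
#' Nonparametric two-tailed comparison of per-unit electrode maps (e.g.
#' stimulation-window mean baseline-normalized PLV at the individual alpha
#' frequency, one value per electrode per subject or replicate).  A
#' per-electrode t statistic (dependent for paired designs, pooled-variance
#' independent otherwise) is thresholded at the parametric critical value
#' (`alpha`, two-tailed); suprathreshold electrodes of equal sign are
#' grouped into spatially connected clusters via the neighbor graph;
#' cluster mass is the sum of t within a cluster.  The null distribution of
#' the maximum absolute cluster mass is obtained from `n_perm` random sign
#' flips (paired) or label shuffles (independent), and each observed
#' cluster gets the Monte-Carlo p-value `(r + 1) / (n_perm + 1)`.
#'
#' @param a,b Numeric unit x electrode matrices (equal column count; equal
#'   row count and matched ordering when `paired`).
#' @param nb A [build_neighbors()] graph whose labels match the columns of
#'   `a`/`b` (columns are matched by name when dimnames are present,
#'   otherwise by position).
#' @param paired Dependent (sign-flip) or independent (shuffle) design.
#' @param n_perm Number of randomizations (default 1000, `>= 100`).
#' @param alpha Cluster-forming threshold (per-electrode two-tailed level,
#'   default 0.05).
#' @param seed Integer seed; results are deterministic per seed.
#' @return Object of class `ClusterTestResult`: per-electrode `t`,
#'   `clusters` (list of electrode index vectors), `cluster_mass`,
#'   `p` (per cluster), `n_perm`, `type`, `alpha`.
#' @export
cluster_permutation_test <- function(a, b, nb, paired = TRUE,
                                     n_perm = 1000L, alpha = 0.05,
                                     seed = 1L) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != ncol(b))
    stop("cluster_permutation_test: electrode counts differ")
  nel <- ncol(a)
  if (!length(nb$labels) || !any(nb$adjacency))
    stop("cluster_permutation_test: empty neighbor graph")
  if (!is.null(colnames(a)) && all(colnames(a) %in% nb$labels)) {
    adj <- nb$adjacency[colnames(a), colnames(a)]
  } else {
    if (length(nb$labels) != nel)
      stop("cluster_permutation_test: neighbor graph does not cover electrodes")
    adj <- nb$adjacency
  }
  if (n_perm < 100L) stop("cluster_permutation_test: n_perm must be >= 100")
  if (paired && nrow(a) != nrow(b))
    stop("cluster_permutation_test: paired design needs equal unit counts")
  adj_list <- apply(adj, 1, which, simplify = FALSE)

  if (paired) {
    d <- a - b
    n <- nrow(d)
    tcrit <- stats::qt(1 - alpha / 2, df = n - 1)
    tstat <- function(dd) {
      m <- colMeans(dd)
      s <- sqrt((colSums(dd^2) - n * m^2) / (n - 1))
      m / (s / sqrt(n))
    }
    t_obs <- tstat(d)
  } else {
    n1 <- nrow(a); n2 <- nrow(b)
    tcrit <- stats::qt(1 - alpha / 2, df = n1 + n2 - 2)
    pooled <- rbind(a, b)
    tstat2 <- function(idx1) {
      x <- pooled[idx1, , drop = FALSE]
      y <- pooled[-idx1, , drop = FALSE]
      mx <- colMeans(x); my <- colMeans(y)
      vx <- (colSums(x^2) - n1 * mx^2) / (n1 - 1)
      vy <- (colSums(y^2) - n2 * my^2) / (n2 - 1)
      sp <- sqrt(((n1 - 1) * vx + (n2 - 1) * vy) / (n1 + n2 - 2))
      (mx - my) / (sp * sqrt(1 / n1 + 1 / n2))
    }
    t_obs <- tstat2(seq_len(n1))
  }

  obs <- cluster_masses(t_obs, tcrit, adj_list)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    tp <- if (paired) {
      tstat(d * sample(c(-1, 1), nrow(d), replace = TRUE))
    } else {
      tstat2(sample.int(nrow(pooled), nrow(a)))
    }
    cm <- cluster_masses(tp, tcrit, adj_list)
    null_max[p] <- if (length(cm$mass)) max(abs(cm$mass)) else 0
  }
  pvals <- vapply(obs$mass, function(m)
    (sum(null_max >= abs(m)) + 1) / (n_perm + 1), 0)
  structure(list(t = t_obs, clusters = obs$members, cluster_mass = obs$mass,
                 p = pvals, n_perm = as.integer(n_perm),
                 type = if (paired) "dependent" else "independent",
                 alpha = alpha, tcrit = tcrit,
                 electrode_names = colnames(a) %||% nb$labels),
            class = "ClusterTestResult")
}

# connected clusters of same-sign suprathreshold electrodes; mass = sum(t)
cluster_masses <- function(t, tcrit, adj_list) {
  supra <- which(abs(t) > tcrit)
  if (!length(supra)) return(list(members = list(), mass = numeric(0)))
  sgn <- sign(t)
  seen <- logical(length(t))
  members <- list(); mass <- numeric(0)
  for (s in supra) {
    if (seen[s]) next
    comp <- s; seen[s] <- TRUE; frontier <- s
    while (length(frontier)) {
      nxt <- unique(unlist(adj_list[frontier], use.names = FALSE))
      nxt <- nxt[!seen[nxt] & abs(t[nxt]) > tcrit & sgn[nxt] == sgn[s]]
      seen[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    members[[length(members) + 1L]] <- sort(comp)
    mass <- c(mass, sum(t[comp]))
  }
  list(members = members, mass = mass)
}

#' @export
print.ClusterTestResult <- function(x, ...) {
  cat(sprintf("ClusterTestResult (%s t, %d permutations): %d cluster(s)\n",
              x$type, x$n_perm, length(x$clusters)))
  for (i in seq_along(x$clusters))
    cat(sprintf("  cluster %d: %d electrodes, mass %.2f, p = %.4g\n",
                i, length(x$clusters[[i]]), x$cluster_mass[i], x$p[i]))
  invisible(x)
}
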