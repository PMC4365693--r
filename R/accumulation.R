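# Core/pan-genome rarefaction and the open-pangenome power law.
#
# The rarefaction protocol follows the classical repeated-random-subsampling
# design: for each number of genomes n, draw random n-genome subsets without
# replacement, count the CLOGs shared by all sampled genomes (core) and the
# CLOGs touched by any of them (pan), and summarize over replicates. The
# number of genes new to the collection when the n-th genome is added decays
# as kappa * n^(-alpha) for an open pan-genome; only for alpha > 1 does the
# pan-genome size approach a limit.

all_permutations <- function(G) {
  rec <- function(v) {
    if (length(v) <= 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(rec(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  rec(seq_len(G))
}

#' Core/pan-genome rarefaction by random genome subsampling
#'
#' For each n in 1..G draws \code{repetitions} uniform random subsets of n
#' genomes (without replacement within a subset, independent across
#' replicates) and records the core and pan CLOG counts of each subset. With
#' \code{nested = TRUE} each replicate instead draws one random genome
#' ordering and scores its prefixes, so core is non-increasing and pan
#' non-decreasing along every replicate.
#'
#' When fewer than \code{repetitions} distinct subsets exist at some n
#' (e.g. n = G has a single subset), all distinct subsets are enumerated
#' once instead of sampled, so replicate means at those n are exact.
#'
#' @param table a \code{\link{clog_table}}
#' @param repetitions number of random subsets per n (>= 1)
#' @param seed RNG seed (required; logged in the result)
#' @param nested use prefix (accumulation-curve) sampling instead of
#'   independent subsets (every n then keeps \code{repetitions} values)
#' @return object of class \code{rarefaction_curve}: lists \code{core} and
#'   \code{pan} with one integer vector of replicate values per n (length
#'   \code{repetitions}, or the number of distinct subsets if smaller),
#'   plus \code{genomes}, \code{repetitions}, \code{seed}, \code{nested}.
#' @export
rarefy <- function(table, repetitions = 1000, seed, nested = FALSE) {
  stopifnot(inherits(table, "clog_table"))
  if (repetitions < 1) stop2("repetitions must be >= 1")
  G <- length(table$genomes)
  if (G == 0L) stop2("genome universe is empty")
  if (n_clogs(table) == 0L) stop2("CLOG table is empty")
  p <- presence_matrix(table) * 1L
  R <- as.integer(repetitions)
  core <- vector("list", G)
  pan <- vector("list", G)
  with_seed(seed, {
    if (nested) {
      cm <- matrix(NA_integer_, R, G)
      pm <- matrix(NA_integer_, R, G)
      for (r in seq_len(R)) {
        ord <- sample.int(G)
        cnt <- integer(nrow(p))
        for (n in seq_len(G)) {
          cnt <- cnt + p[, ord[n]]
          cm[r, n] <- sum(cnt == n)
          pm[r, n] <- sum(cnt > 0L)
        }
      }
      for (n in seq_len(G)) { core[[n]] <- cm[, n]; pan[[n]] <- pm[, n] }
    } else {
      for (n in seq_len(G)) {
        if (choose(G, n) <= R) {
          sel <- utils::combn(G, n, function(idx) {
            v <- integer(G); v[idx] <- 1L; v
          })
        } else {
          sel <- matrix(0L, G, R)
          for (r in seq_len(R)) sel[sample.int(G, n), r] <- 1L
        }
        cnt <- p %*% sel
        core[[n]] <- as.integer(colSums(cnt == n))
        pan[[n]] <- as.integer(colSums(cnt > 0L))
      }
    }
  })
  names(core) <- names(pan) <- as.character(seq_len(G))
  structure(list(core = core, pan = pan, genomes = table$genomes,
                 repetitions = R, seed = seed, nested = nested),
            class = "rarefaction_curve")
}

#' Five-number summaries of a rarefaction curve
#'
#' @param object a \code{rarefaction_curve}
#' @param statistic \code{"core"} or \code{"pan"}
#' @param ... unused
#' @return data.frame with n, mean, min, q1, median, q3, max
#' @export
summary.rarefaction_curve <- function(object, statistic = c("core", "pan"),
                                      ...) {
  statistic <- match.arg(statistic)
  reps <- object[[statistic]]
  qs <- vapply(reps, stats::quantile, numeric(5),
               probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  data.frame(n = seq_along(reps),
             mean = vapply(reps, mean, numeric(1)),
             min = qs[1, ], q1 = qs[2, ], median = qs[3, ], q3 = qs[4, ],
             max = qs[5, ], row.names = NULL)
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  G <- length(x$core)
  cat("Rarefaction curve over", G, "genomes,", x$repetitions,
      "replicates (seed", paste0(x$seed, ")"),
      if (x$nested) "[nested]" else "", "\n")
  cat("  mean core at n=G:", mean(x$core[[G]]),
      "; mean pan at n=G:", mean(x$pan[[G]]), "\n")
  invisible(x)
}

#' New CLOGs per added genome over random orderings
#'
#' For each of \code{permutations} random genome orderings, counts the CLOGs
#' first encountered at position n (so that, per ordering,
#' pan(G) = pan(1) + sum of new(n) over n = 2..G). When G! does not exceed
#' \code{permutations}, all orderings are enumerated once instead of
#' sampled, making the per-step means exact.
#'
#' @param table a \code{\link{clog_table}}
#' @param permutations number of random orderings (>= 1)
#' @param seed RNG seed
#' @return object of class \code{new_genes_curve}: matrix \code{new}
#'   (one row per ordering; column n = CLOGs first seen at step n),
#'   \code{mean}, \code{sd} per n, \code{seed}.
#' @export
new_genes_per_step <- function(table, permutations = 1000, seed) {
  stopifnot(inherits(table, "clog_table"))
  if (permutations < 1) stop2("permutations must be >= 1")
  G <- length(table$genomes)
  if (G == 0L || n_clogs(table) == 0L) stop2("empty table")
  p <- presence_matrix(table)
  P <- as.integer(permutations)
  exhaustive <- factorial(G) <= P
  orderings <- if (exhaustive) all_permutations(G) else NULL
  if (exhaustive) P <- length(orderings)
  new <- matrix(NA_integer_, P, G)
  with_seed(seed, {
    for (r in seq_len(P)) {
      ord <- if (exhaustive) orderings[[r]] else sample.int(G)
      rank_of <- integer(G); rank_of[ord] <- seq_len(G)
      # first step at which each CLOG is touched
      first <- rep.int(G + 1L, nrow(p))
      for (j in seq_len(G)) {
        hit <- p[, j]
        first[hit] <- pmin(first[hit], rank_of[j])
      }
      new[r, ] <- tabulate(first, nbins = G)
    }
  })
  colnames(new) <- as.character(seq_len(G))
  structure(list(new = new, mean = colMeans(new), sd = apply(new, 2, stats::sd),
                 permutations = P, seed = seed),
            class = "new_genes_curve")
}

#' @export
print.new_genes_curve <- function(x, ...) {
  cat("New-CLOGs-per-genome curve,", x$permutations,
      "orderings (seed", paste0(x$seed, ")\n"))
  print(round(x$mean, 1))
  invisible(x)
}

#' Fit the open-pangenome power law
#'
#' Fits mean new(n) = kappa * n^(-alpha) by least squares on
#' log(mean new(n)) versus log(n) for n >= \code{n_min}. The spread of
#' alpha is estimated by bootstrap over orderings: orderings are resampled
#' with replacement, per-n means recomputed and the regression refitted.
#' A pan-genome is called \emph{open} when alpha <= 1 (only for alpha > 1
#' does a limit exist).
#'
#' @param new_curve a \code{new_genes_curve} (or a data.frame with columns
#'   \code{n} and \code{mean})
#' @param n_min smallest n entering the fit (default 2: the first genome
#'   measures genome size, not discovery rate)
#' @param bootstrap number of bootstrap refits for \code{alpha_sd}
#'   (0 disables; needs a \code{new_genes_curve} with raw replicates)
#' @param seed RNG seed for the bootstrap (required when bootstrap > 0)
#' @return object of class \code{power_law_fit}: \code{alpha}, \code{kappa},
#'   \code{alpha_sd}, \code{r_squared}, \code{n_range}, \code{open}
#' @examples
#' curve <- data.frame(n = 1:20, mean = 100 * (1:20)^-0.5)
#' fit_power_law(curve)$alpha   # 0.5 exactly
#' @export
fit_power_law <- function(new_curve, n_min = 2, bootstrap = 100, seed = NULL) {
  if (inherits(new_curve, "new_genes_curve")) {
    df <- data.frame(n = seq_along(new_curve$mean), mean = new_curve$mean)
    raw <- new_curve$new
  } else {
    df <- as.data.frame(new_curve)
    stopifnot(all(c("n", "mean") %in% names(df)))
    raw <- NULL
    bootstrap <- 0
  }
  use <- df$n >= n_min
  if (any(use & df$mean <= 0)) {
    warning("dropping ", sum(use & df$mean <= 0),
            " point(s) with non-positive mean new(n)")
    use <- use & df$mean > 0
  }
  if (sum(use) < 3) stop2("fewer than 3 usable points for the power-law fit")
  fit <- stats::lm(log(mean) ~ log(n), data = df[use, ])
  alpha <- -unname(stats::coef(fit)[2])
  kappa <- exp(unname(stats::coef(fit)[1]))
  y <- log(df$mean[use])
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  alpha_sd <- NA_real_
  if (bootstrap > 0 && !is.null(raw)) {
    if (is.null(seed)) stop2("a seed is required for the bootstrap")
    ns <- df$n[use]
    alphas <- with_seed(seed, vapply(seq_len(bootstrap), function(b) {
      idx <- sample.int(nrow(raw), replace = TRUE)
      mb <- colMeans(raw[idx, ns, drop = FALSE])
      keep <- mb > 0
      if (sum(keep) < 3) return(NA_real_)
      -unname(stats::coef(stats::lm(log(mb[keep]) ~ log(ns[keep])))[2])
    }, numeric(1)))
    alpha_sd <- stats::sd(alphas, na.rm = TRUE)
  }
  structure(list(alpha = alpha, kappa = kappa, alpha_sd = alpha_sd,
                 r_squared = r2, n_range = range(df$n[use]),
                 open = alpha <= 1),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit: new(n) = %.3g * n^(-%.3f)\n", x$kappa, x$alpha))
  cat(sprintf("  alpha = %.3f +/- %s, R^2 = %.4f, n in [%d, %d] -> %s pan-genome\n",
              x$alpha,
              if (is.na(x$alpha_sd)) "NA" else sprintf("%.3f", x$alpha_sd),
              x$r_squared, x$n_range[1], x$n_range[2],
              if (x$open) "open" else "closed"))
  invisible(x)
}

#' Observed-over-expected clade core-genome ratio
#'
#' Compares the core-genome size of a clade (CLOGs covering every clade
#' member, computed on the full table) with the mean core size of random
#' genome subsets of the same cardinality.
#'
#' @param table a \code{\link{clog_table}}
#' @param clade genome ids (subset of the universe, size >= 2)
#' @param curve a \code{rarefaction_curve} computed on the same table
#' @return list with \code{observed}, \code{expected}, \code{ratio}
#' @export
core_ratio <- function(table, clade, curve) {
  stopifnot(inherits(table, "clog_table"),
            inherits(curve, "rarefaction_curve"))
  clade <- as.character(clade)
  if (length(clade) < 2) stop2("clade must contain at least 2 genomes")
  bad <- setdiff(clade, table$genomes)
  if (length(bad)) stop2("not in universe: ", paste(bad, collapse = ", "))
  if (!identical(curve$genomes, table$genomes))
    stop2("curve was computed on a different genome universe")
  p <- presence_matrix(table)
  observed <- sum(rowSums(p[, clade, drop = FALSE]) == length(clade))
  expected <- mean(curve$core[[length(clade)]])
  list(observed = observed, expected = expected,
       ratio = observed / expected)
}
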