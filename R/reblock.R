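#' Reblocking analysis of a correlated time series
#'
#' Flyvbjerg-Petersen successive pairwise block averaging: at each level
#' the series is halved by averaging neighbouring pairs and the naive
#' standard error of the blocked series is recorded.  For a correlated
#' series the SEM estimate grows with block size until blocks are longer
#' than the correlation time, then plateaus.  The plateau is selected
#' automatically as the smallest level whose SEM changes over the next
#' two doublings stay below max(5%, sqrt(8 / n_blocks)); the second term
#' keeps the 5% rule from being defeated by the chi-square sampling
#' noise of the blocked SEM estimate itself (relative sd about
#' sqrt(1 / 2 n_blocks)) once few blocks remain.  If no level qualifies,
#' the largest level with at least 32 blocks is used and flagged.
#'
#' @param series numeric vector, length >= 64.
#' @param plateau_rtol relative SEM change defining the plateau.
#' @return list with `mean`, `sem`, `table` (data.frame: level, block
#'   size, n blocks, sem), `plateau_level`, `converged`.
#' @export
reblock <- function(series, plateau_rtol = 0.05) {
  n <- length(series)
  if (n < 64) stop("too short to reblock (need >= 64 samples)")
  x <- series
  sems <- numeric(0)
  sizes <- integer(0)
  counts <- integer(0)
  level <- 0L
  repeat {
    m <- length(x)
    sems <- c(sems, stats::sd(x) / sqrt(m))
    sizes <- c(sizes, as.integer(2^level))
    counts <- c(counts, m)
    if (m < 32) break
    if (m %% 2 == 1) x <- x[-m]
    x <- (x[seq(1, length(x), 2)] + x[seq(2, length(x), 2)]) / 2
    level <- level + 1L
  }
  tab <- data.frame(level = seq_along(sems) - 1L, block_size = sizes,
                    n_blocks = counts, sem = sems)
  # constant series: SEM identically zero at every level
  if (all(sems == 0))
    return(list(mean = mean(series), sem = 0, table = tab,
                plateau_level = 0L, converged = TRUE))
  plateau <- NA_integer_
  for (l in seq_len(length(sems) - 2)) {
    s <- sems[l]
    tol <- max(plateau_rtol, sqrt(8 / counts[l]))
    if (s > 0 &&
        abs(sems[l + 1] - s) / s < tol &&
        abs(sems[l + 2] - s) / s < tol) {
      plateau <- l
      break
    }
  }
  converged <- !is.na(plateau)
  if (!converged) plateau <- max(which(counts >= 32))
  list(mean = mean(series), sem = sems[plateau], table = tab,
       plateau_level = tab$level[plateau], converged = converged)
}
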