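# Independent nested-bisection oracle for the free-metal concentration.
#
# The metal mass balance is reduced to one dimension: for a trial free metal
# concentration m, the chelator balance is solved for the free (uncomplexed)
# ligand l by bisection in log10 l, the peptide balance has a closed form,
# and the implied total metal is monotone in m, so m itself is found by
# bisection in log10 m. Entirely independent of the Newton-Raphson solver.
oracle_free_metal <- function(totals, chelator = NULL, peptide = NULL,
                              bits = 200) {
  TM <- totals$metal; TL <- totals$chelator; TP <- totals$peptide
  if (TM <= 0) return(0)
  sp <- if (!is.null(chelator) && TL > 0)
    conditional_constants(chelator, totals$pH) else NULL
  beta <- if (!is.null(sp)) 10 ^ sp$log10_beta_cond else numeric()

  chel_l <- function(m) {
    if (is.null(sp)) return(0)
    g <- function(log_l) {
      l <- 10 ^ log_l
      l + sum(sp$l * beta * m ^ sp$m * l ^ sp$l) - TL
    }
    lo <- log10(TL) - 40; hi <- log10(TL)
    for (i in seq_len(bits)) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
    }
    10 ^ ((lo + hi) / 2)
  }
  K1 <- if (!is.null(peptide)) peptide$K1 else 0
  K2 <- if (!is.null(peptide) && !is.null(peptide$K2)) peptide$K2 else 0

  implied_TM <- function(log_m) {
    m <- 10 ^ log_m
    l <- chel_l(m)
    bound_ch <- if (is.null(sp)) 0 else
      sum(sp$m * beta * m ^ sp$m * l ^ sp$l)
    bound_p <- if (TP > 0 && K1 > 0) {
      p <- TP / (1 + K1 * m + K1 * K2 * m^2)
      K1 * m * p + 2 * K1 * K2 * m^2 * p
    } else 0
    m + bound_ch + bound_p
  }
  lo <- log10(TM) - 40; hi <- log10(TM)
  for (i in seq_len(bits)) {
    mid <- (lo + hi) / 2
    if (implied_TM(mid) > TM) hi <- mid else lo <- mid
  }
  10 ^ ((lo + hi) / 2)
}

# random speciation system generator used by the property tests
random_system <- function() {
  n_ch <- sample(1:3, 1)
  stepwise <- sort(stats::runif(n_ch, 4, 12), decreasing = TRUE)
  ch <- chelator_model(
    pKa = sort(stats::runif(sample(1:3, 1), 2, 10), decreasing = TRUE),
    species = data.frame(m = rep(1L, n_ch), l = seq_len(n_ch),
                         log10_beta = cumsum(stepwise)))
  n_sites <- sample(1:2, 1)
  pep <- if (n_sites == 1) peptide_model(1, 10 ^ stats::runif(1, 4, 12))
  else peptide_model(2, 10 ^ stats::runif(1, 4, 12),
                     10 ^ stats::runif(1, 4, 12))
  tot <- component_totals(10 ^ stats::runif(1, -7, -3),
                          10 ^ stats::runif(1, -7, -3),
                          10 ^ stats::runif(1, -7, -3),
                          pH = stats::runif(1, 4, 9))
  list(totals = tot, chelator = ch, peptide = pep)
}
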