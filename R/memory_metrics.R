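#' Memory selectivity of one neuron
#'
#' Compares the summed input weight over the memory-A unit set against the
#' memory-B set: 1 if A dominates, -1 if B dominates, 0 on exact equality
#' (strict comparison; with continuous weights ties have probability ~0).
#'
#' @param w_row weight (or gain) vector over all input units.
#' @param memory_a,memory_b input id sets partitioning the units.
#' @return one of 1, -1, 0.
#' @export
selectivity <- function(w_row, memory_a, memory_b) {
  if (length(intersect(memory_a, memory_b)) > 0L ||
      !setequal(c(memory_a, memory_b), seq_along(w_row))) {
    stop("memory sets must partition the inputs", call. = FALSE)
  }
  sign(sum(w_row[memory_a]) - sum(w_row[memory_b]))
}

#' Memory selectivity of every neuron in a weight matrix
#' @param W neurons x inputs weight (or gain) matrix.
#' @param memory_a,memory_b input id sets partitioning the columns.
#' @return integer vector of 1 / -1 / 0 per neuron.
#' @export
selectivity_matrix <- function(W, memory_a, memory_b) {
  if (length(intersect(memory_a, memory_b)) > 0L ||
      !setequal(c(memory_a, memory_b), seq_len(ncol(W)))) {
    stop("memory sets must partition the inputs", call. = FALSE)
  }
  as.integer(sign(rowSums(W[, memory_a, drop = FALSE]) -
                  rowSums(W[, memory_b, drop = FALSE])))
}

#' LTP-imposed selectivity
#'
#' The selectivity the embossing gain pattern would impose: the selectivity
#' of the theta rows themselves.
#'
#' @param theta_row embossing gain vector of one neuron (or pass a matrix to
#'   [selectivity_matrix()]).
#' @inheritParams selectivity
#' @return one of 1, -1, 0.
#' @export
ltp_selectivity <- function(theta_row, memory_a, memory_b) {
  selectivity(theta_row, memory_a, memory_b)
}

#' Proportion of selectivity switches during sleep
#'
#' A neuron switched when the product of its pre-sleep and final
#' selectivities is -1; neurons with a zero selectivity at either time count
#' as neither switched nor stable (the Heaviside step of a non-positive
#' argument is taken as 0).
#'
#' @param sel_sleep selectivity vector at sleep onset.
#' @param sel_final selectivity vector at the end of the run.
#' @return `T_S` in `[0, 1]`.
#' @export
proportion_switches <- function(sel_sleep, sel_final) {
  if (length(sel_sleep) != length(sel_final)) {
    stop("length mismatch", call. = FALSE)
  }
  mean(sel_sleep * sel_final == -1)
}

#' Proportion of LTP hits
#'
#' A hit is a neuron whose final selectivity equals the selectivity imposed
#' by the embossing gain pattern (product +1); zeros count as misses.
#'
#' @param sel_theta LTP-imposed selectivity vector.
#' @param sel_final selectivity vector at the end of the run.
#' @return `T_H` in `[0, 1]`.
#' @export
proportion_hits <- function(sel_theta, sel_final) {
  if (length(sel_theta) != length(sel_final)) {
    stop("length mismatch", call. = FALSE)
  }
  mean(sel_theta * sel_final == 1)
}

#' Surrogate shuffle significance test
#'
#' Shuffles the post-sleep selectivity labels across neurons, recomputes the
#' statistic for each shuffle, fits a normal distribution to the surrogate
#' values and reports the two-sided p-value of the observed statistic
#' together with the (p > 0.05) non-significance interval.
#'
#' @param sel_ref reference selectivity vector (pre-sleep selectivity for
#'   the switch statistic, LTP-imposed selectivity for the hit statistic).
#' @param sel_final post-sleep selectivity vector (this one is shuffled).
#' @param statistic `"switch"` (T_S) or `"hit"` (T_H).
#' @param n_surrogates number of shuffles (200).
#' @param seed optional integer seed.
#' @return list with `observed`, `surrogate_mean`, `surrogate_sd`,
#'   `p_value`, `nonsig_interval` (mean +/- 1.96 sd) and `significant`
#'   (p < 0.05). A degenerate (constant) surrogate distribution yields
#'   `p_value = NA` with a warning.
#' @export
surrogate_test <- function(sel_ref, sel_final,
                           statistic = c("switch", "hit"),
                           n_surrogates = 200L, seed = NULL) {
  statistic <- match.arg(statistic)
  if (length(sel_ref) != length(sel_final)) stop("length mismatch",
                                                 call. = FALSE)
  if (n_surrogates < 2L) stop("need at least 2 surrogates", call. = FALSE)
  .seed_if_given(seed)
  stat_fun <- if (statistic == "switch") proportion_switches else
    proportion_hits
  observed <- stat_fun(sel_ref, sel_final)
  sur <- vapply(seq_len(n_surrogates), function(k) {
    stat_fun(sel_ref, sample(sel_final))
  }, numeric(1))
  mu <- mean(sur)
  s <- stats::sd(sur)
  if (!is.finite(s) || s == 0) {
    warning("degenerate surrogate distribution: p-value undefined")
    return(list(observed = observed, surrogate_mean = mu, surrogate_sd = s,
                p_value = NA_real_, nonsig_interval = c(mu, mu),
                significant = NA))
  }
  p <- 2 * stats::pnorm(-abs(observed - mu) / s)
  ci <- mu + c(-1, 1) * stats::qnorm(0.975) * s
  list(observed = observed, surrogate_mean = mu, surrogate_sd = s,
       p_value = p, nonsig_interval = ci, significant = p < 0.05)
}
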