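# Shared fixtures, built in code.

# Small, quickly clusterable cohort for module-level tests.
small_cohort <- function(seed = 7, n_genes = 300L, shift = 2.5, noise = 0.4) {
  simulate_cohort(cohort_config(n_genes = n_genes,
                                markers_per_subtype = 20L,
                                marker_log2_shift = shift,
                                noise_sd = noise, seed = seed))
}

surv_records <- function(clinical, labels = clinical$subtype_true) {
  data.frame(time = clinical$time_months, event = clinical$event,
             group = labels)
}

# Hand log-rank oracle: O - E / V tabulation over distinct event times.
logrank_by_hand <- function(records, a, b) {
  sub <- records[records$group %in% c(a, b), ]
  times <- sort(unique(sub$time[sub$event == 1]))
  OE <- 0; V <- 0
  for (t in times) {
    at_risk <- sub$time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & sub$group == a)
    d <- sum(sub$time == t & sub$event == 1)
    d1 <- sum(sub$time == t & sub$event == 1 & sub$group == a)
    OE <- OE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- OE^2 / V
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# Exhaustive two-sided Fisher oracle for a 2x2 table: sum the
# hypergeometric point probabilities not exceeding the observed one.
fisher_by_enumeration <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Heavy rank-selection sweep shared by the recovery checks; computed once.
.sweep_cache <- new.env(parent = emptyenv())

rank_selection_sweep <- function(n_seeds = 20L) {
  key <- paste0("s", n_seeds)
  if (!is.null(.sweep_cache[[key]])) return(.sweep_cache[[key]])
  out <- lapply(seq_len(n_seeds), function(s) {
    co <- simulate_cohort(cohort_config(seed = 100L + s))
    A <- exponential_scale(co$expression)
    sel <- select_rank(A, k_min = 2, k_max = 4, n_runs = 20,
                       base_seed = 100L + s)
    list(cophenetic = sel$cophenetic, k_star = sel$k_star,
         labels = sel$results[[paste0("k", sel$k_star)]]$labels,
         labels_k3 = sel$results$k3$labels,
         truth = co$truth$labels)
  })
  .sweep_cache[[key]] <- out
  out
}
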