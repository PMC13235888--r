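# Patient-level, label-stratified train/validation/test splits. All
# instances of a patient share that patient's set, so no waveform can
# leak across sets.

# largest-remainder apportionment of n into parts proportional to p
largest_remainder <- function(n, p) {
  exact <- n * p / sum(p)
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- exact - base
    # deterministic tie-break: earlier part first
    ord <- order(-frac, seq_along(p))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Patient-level stratified split plan
#'
#' For each repeat, patients are partitioned into train/validation/test
#' sets. Global set sizes follow `ratios` by largest-remainder rounding;
#' within that, class quotas are apportioned so each set keeps both
#' classes. Deterministic under `seed`; each repeat uses a distinct
#' derived sub-seed.
#'
#' @param patient_ids Character vector of patient identifiers.
#' @param labels 0/1 outcome per patient.
#' @param ratios Train/validation/test fractions (sum to 1).
#' @param n_repeats Number of independent repeats.
#' @param seed Master seed.
#' @return A `split_plan`: `assignments` is a list (one per repeat) of
#'   data frames with `patient_id`, `label`, `set`.
#' @export
make_splits <- function(patient_ids, labels, ratios = c(0.70, 0.15, 0.15),
                        n_repeats = 5, seed = 1) {
  stopifnot(length(patient_ids) == length(labels),
            !anyDuplicated(patient_ids),
            length(ratios) == 3, abs(sum(ratios) - 1) < 1e-9)
  n <- length(patient_ids)
  classes <- sort(unique(labels))
  n_per_class <- table(factor(labels, levels = classes))
  if (any(n_per_class < 3))
    stop("infeasible stratification: every class needs >= 3 patients")
  sizes <- largest_remainder(n, ratios)  # train, val, test
  if (any(sizes < length(classes)))
    stop("infeasible stratification: a set is smaller than the class count")
  assignments <- lapply(seq_len(n_repeats), function(rep_i) {
    with_seed(mix_seed(seed, rep_i), {
      # per-class largest-remainder quotas
      quota <- sapply(classes, function(cl)
        largest_remainder(sum(labels == cl), ratios))  # 3 x n_classes
      # ensure every class appears in every set
      for (ci in seq_along(classes)) for (k in 2:3) {
        if (quota[k, ci] == 0 && quota[1, ci] > 1) {
          quota[k, ci] <- 1L; quota[1, ci] <- quota[1, ci] - 1L
        }
      }
      # repair column sums to the global set sizes
      repeat {
        tot <- rowSums(quota)
        over <- which(tot > sizes); under <- which(tot < sizes)
        if (!length(over) || !length(under)) break
        k_o <- over[1]; k_u <- under[1]
        ci <- which.max(quota[k_o, ])  # move from the largest class
        quota[k_o, ci] <- quota[k_o, ci] - 1L
        quota[k_u, ci] <- quota[k_u, ci] + 1L
      }
      set_names <- c("train", "val", "test")
      out <- data.frame(patient_id = patient_ids, label = labels,
                        set = NA_character_, stringsAsFactors = FALSE)
      for (ci in seq_along(classes)) {
        members <- sample(which(labels == classes[ci]))
        sets <- rep(set_names, times = quota[, ci])
        out$set[members] <- sets
      }
      out
    })
  })
  structure(list(assignments = assignments, ratios = ratios,
                 n_repeats = n_repeats, seed = seed),
            class = "split_plan")
}

#' Assert that a split plan has no patient-level leakage
#'
#' @param plan A `split_plan`.
#' @return `TRUE` invisibly; errors if any repeat assigns a patient to
#'   more than one set or misses a patient.
#' @export
check_no_leakage <- function(plan) {
  stopifnot(inherits(plan, "split_plan"))
  for (asg in plan$assignments) {
    if (anyDuplicated(asg$patient_id))
      stop("patient assigned to multiple sets")
    if (any(is.na(asg$set)))
      stop("unassigned patient in split plan")
  }
  invisible(TRUE)
}
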