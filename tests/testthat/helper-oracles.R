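# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# Per-base intensity counter: walks every base of the region and counts
# reads covering it.
oracle_intensity <- function(reads, region) {
  if (region$end <= region$start) return(0)
  bases <- seq(region$start, region$end - 1)
  total <- 0
  for (i in seq_len(nrow(reads))) {
    if (reads$chrom[i] != region$chrom) next
    total <- total + sum(bases >= reads$start[i] & bases < reads$end[i])
  }
  total
}

# Exhaustive segmentation: enumerate all 2^(n-1) cut sets of an interval and
# keep the unique one whose cuts are exactly the sub-threshold adjacencies.
oracle_split <- function(r, threshold) {
  n_adj <- length(r)
  if (n_adj == 0) return(rep(1L, 1))
  best <- NULL
  for (mask in 0:(2^n_adj - 1)) {
    cuts <- as.logical(bitwAnd(mask, 2^(seq_len(n_adj) - 1)))
    if (all(cuts == (r < threshold))) {
      best <- cuts
      break
    }
  }
  cumsum(c(TRUE, best))
}

# Direct enumeration of one-sided permutation p-values for a small intensity
# matrix: recomputes M for every case-group choice by explicit looping.
oracle_perm_p <- function(values, group, region_lengths, m_obs, direction,
                          beta = 10, L = 36, n_strata = 1) {
  n <- length(group)
  k <- sum(group == "case")
  combs <- utils::combn(n, k)
  null_scores <- c()
  for (j in seq_len(ncol(combs))) {
    case_idx <- combs[, j]
    for (i in seq_len(nrow(values))) {
      ic <- mean(values[i, case_idx])
      in_ <- mean(values[i, -case_idx])
      null_scores <- c(null_scores,
                       log2((ic + beta * L) / (in_ + beta * L)))
    }
  }
  vapply(seq_along(m_obs), function(i) {
    if (direction[i] == "hyper") {
      (1 + sum(null_scores >= m_obs[i])) / (1 + length(null_scores))
    } else {
      (1 + sum(null_scores <= m_obs[i])) / (1 + length(null_scores))
    }
  }, numeric(1))
}

# Tiny deterministic fixture: a 4-region, 2v2 intensity matrix
tiny_matrix <- function() {
  list(
    mat = tibble::tibble(
      region_id = paste0("r", 1:4),
      c1 = c(700, 100, 400, 0), c2 = c(740, 140, 380, 0),
      k1 = c(350, 120, 400, 0), k2 = c(370, 90, 420, 0)
    ),
    samples = tibble::tibble(
      sample_id = c("c1", "c2", "k1", "k2"),
      group = c("case", "case", "control", "control")
    ),
    regions = tibble::tibble(
      region_id = paste0("r", 1:4), role = "unit", n_sites = c(2, 3, 5, 4)
    )
  )
}
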