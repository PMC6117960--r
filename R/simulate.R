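#' Simulate a toy genome: TSS table, CpG sites, chromosome sizes
#'
#' Lays out non-overlapping genes (one toy chromosome per 500 promoters)
#' with a TSS, a first exon, and a cluster of CpG sites inside each
#' promoter window. Inter-site gaps are drawn from a mixture of short gaps
#' (within-interval spacing) and occasional long gaps above typical merge
#' thresholds, so the same genome exercises both the merge and the split
#' paths of segmentation.
#'
#' @param n_promoters Number of genes/promoters.
#' @param mean_cpg Poisson mean for the number of CpG sites per promoter
#'   (default 8); a promoter may draw zero sites.
#' @param upstream_bp Promoter upstream extent used for the layout
#'   (default 5000).
#' @param seed RNG seed.
#' @return A list with tibbles `tss`, `sites` (CpG sites, 1 bp each,
#'   sorted), `chrom_sizes`, and `promoters` (via [define_promoters()]).
#' @export
simulate_genome <- function(n_promoters, mean_cpg = 8, upstream_bp = 5000,
                            seed = 1) {
  stopifnot(n_promoters >= 0, mean_cpg > 0)
  per_chrom <- 500
  pitch <- upstream_bp * 2 + 4000  # gene-to-gene spacing, no overlap
  with_rng(seed, {
    if (n_promoters == 0) {
      genome <- list(
        tss = tibble::tibble(gene_id = character(), chrom = character(),
                             strand = character(), tss = numeric(),
                             exon1_start = numeric(), exon1_end = numeric()),
        sites = tibble::tibble(region_id = character(), chrom = character(),
                               start = numeric(), end = numeric(),
                               role = character(), gene_id = character()),
        chrom_sizes = tibble::tibble(chrom = character(), size = numeric())
      )
      genome$promoters <- genome$tss |>
        define_promoters(genome$chrom_sizes, upstream_bp = upstream_bp)
      return(genome)
    }
    idx <- seq_len(n_promoters)
    chrom <- paste0("chr", (idx - 1) %/% per_chrom + 1)
    slot <- (idx - 1) %% per_chrom
    strand <- rep(c("+", "-"), length.out = n_promoters)
    anchor <- slot * pitch + upstream_bp + 1000
    exon_len <- 100 + stats::rpois(n_promoters, 100)
    tss <- ifelse(strand == "+", anchor, anchor + exon_len)
    exon1_start <- anchor
    exon1_end <- anchor + exon_len
    chrom_sizes <- tibble::tibble(
      chrom = unique(chrom),
      size = purrr::map_dbl(unique(chrom), function(ch) {
        max(anchor[chrom == ch]) + exon_len[which.max(anchor * (chrom == ch))] +
          upstream_bp + 2000
      })
    )
    tss_tbl <- tibble::tibble(
      gene_id = sprintf("g%05d", idx), chrom = chrom, strand = strand,
      tss = as.numeric(tss), exon1_start = as.numeric(exon1_start),
      exon1_end = as.numeric(exon1_end)
    )
    promoters <- define_promoters(tss_tbl, chrom_sizes,
                                  upstream_bp = upstream_bp)

    n_sites <- stats::rpois(n_promoters, mean_cpg)
    sites <- purrr::map(which(n_sites > 0), function(i) {
      k <- n_sites[i]
      # short within-cluster gaps, occasionally a long (>300 bp) break
      gaps <- ifelse(stats::runif(k - 1) < 0.2,
                     round(stats::runif(k - 1, 400, 900)),
                     round(stats::runif(k - 1, 15, 120)))
      pos <- promoters$start[i] + 50 + cumsum(c(0, gaps))
      pos <- pos[pos < promoters$end[i] - 1]
      if (length(pos) == 0) return(NULL)
      tibble::tibble(chrom = promoters$chrom[i], start = pos, end = pos + 1,
                     gene_id = promoters$gene_id[i])
    })
    sites <- dplyr::bind_rows(sites)
    if (nrow(sites) > 0) {
      sites <- dplyr::arrange(sites, .data$chrom, .data$start)
      sites <- dplyr::distinct(sites, .data$chrom, .data$start,
                               .keep_all = TRUE)
      sites <- dplyr::mutate(
        sites, region_id = sprintf("cpg_%06d", dplyr::row_number()),
        role = "cpg_site")
      sites <- dplyr::select(sites, "region_id", "chrom", "start", "end",
                             "role", "gene_id")
    } else {
      sites <- tibble::tibble(region_id = character(), chrom = character(),
                              start = numeric(), end = numeric(),
                              role = character(), gene_id = character())
    }
    list(tss = tss_tbl, sites = sites, chrom_sizes = chrom_sizes,
         promoters = promoters)
  })
}

#' Simulate case/control intensities over CpG sites, with planted effects
#'
#' Per-site read counts follow the configured noise family around a
#' site-specific baseline modulated by a latent per-block factor shared by
#' nearby sites: sites within a block have correlated log-means (strength
#' `rho`), sites in different blocks are independent, so segmentation can
#' recover block boundaries from the data. A configured fraction of blocks
#' is planted differential: case-group means are multiplied by `effect`
#' (hypermethylated) or divided by it (hypomethylated), in equal shares.
#'
#' Blocks are defined on the generator side as runs of sites separated by
#' at most 300 bp, each run further cut independently with probability 0.3
#' per adjacency — they play the role of true methylation units.
#'
#' @param genome A genome list from [simulate_genome()].
#' @param samples_per_group Replicates per group (default 3, typical for
#'   capture-based methylation designs at 2–3 per group).
#' @param depth Mean reads per site (default 50).
#' @param dispersion Negative-binomial dispersion (default 0.1); ignored for
#'   `noise = "poisson"`.
#' @param rho Within-block log-mean correlation in `[0, 1]` (default 0.8).
#' @param frac_planted Fraction of blocks planted differential (default 0).
#' @param effect Multiplicative fold on the case mean for planted blocks
#'   (default 4).
#' @param noise `"nb"` (default) or `"poisson"`.
#' @param read_length Read length for the reads output (default 36).
#' @param output `"profiles"` (default) for a per-site intensity tibble, or
#'   `"reads"` to also emit read intervals realising the counts; every read
#'   overlaps its site, so quantifying a window extending `read_length - 1`
#'   bp on both sides of the site recovers the site's profile value exactly.
#' @param seed RNG seed.
#' @return A list: `profiles` (wide site-by-sample intensity tibble, in
#'   bases: read count times `read_length`),
#'   `samples`, `truth` (tibble `block_id`, `site_ids` list-column,
#'   `direction`, `effect`), `blocks`, and `reads` when requested.
#' @export
simulate_intensities <- function(genome, samples_per_group = 3, depth = 50,
                                 dispersion = 0.1, rho = 0.8,
                                 frac_planted = 0, effect = 4,
                                 noise = c("nb", "poisson"),
                                 read_length = 36,
                                 output = c("profiles", "reads"), seed = 1) {
  noise <- match.arg(noise)
  output <- match.arg(output)
  stopifnot(rho >= 0, rho <= 1, frac_planted >= 0, frac_planted < 1,
            effect > 0, depth > 0)
  sites <- genome$sites
  n_sites <- nrow(sites)
  samples <- tibble::tibble(
    sample_id = c(paste0("case_", seq_len(samples_per_group)),
                  paste0("ctrl_", seq_len(samples_per_group))),
    group = rep(c("case", "control"), each = samples_per_group)
  )
  n_samp <- nrow(samples)

  with_rng(seed, {
    # generator-side blocks: gap runs cut further at random adjacencies
    if (n_sites > 0) {
      new_run <- c(TRUE, sites$chrom[-1] != sites$chrom[-n_sites] |
                     sites$start[-1] - sites$end[-n_sites] > 300)
      extra_cut <- stats::runif(n_sites) < 0.3
      extra_cut[new_run] <- FALSE
      block <- cumsum(new_run | extra_cut)
    } else {
      block <- integer(0)
    }
    n_blocks <- length(unique(block))

    planted <- sort(sample.int(n_blocks, size = round(frac_planted * n_blocks)))
    direction <- rep(c("hyper", "hypo"), length.out = length(planted))

    base <- depth * stats::rlnorm(n_sites, 0, 0.3)
    sigma <- 0.4  # latent log-normal scale shared/split by rho
    z_block <- matrix(stats::rnorm(n_blocks * n_samp), n_blocks, n_samp)
    z_site <- matrix(stats::rnorm(n_sites * n_samp), n_sites, n_samp)
    z <- sqrt(rho) * z_block[block, , drop = FALSE] +
      sqrt(1 - rho) * z_site
    mu <- base * exp(sigma * z - sigma^2 / 2)

    is_case <- samples$group == "case"
    eff_row <- rep(1, n_sites)
    if (length(planted) > 0) {
      hyper_blocks <- planted[direction == "hyper"]
      hypo_blocks <- planted[direction == "hypo"]
      eff_row[block %in% hyper_blocks] <- effect
      eff_row[block %in% hypo_blocks] <- 1 / effect
    }
    mu[, is_case] <- mu[, is_case] * eff_row

    counts <- if (noise == "poisson") {
      matrix(stats::rpois(length(mu), lambda = mu), n_sites, n_samp)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             n_sites, n_samp)
    }
    colnames(counts) <- samples$sample_id

    # profiles carry intensity in bases: every read anchored at a site
    # contributes its full length to the site's local methylation signal
    profiles <- dplyr::bind_cols(
      tibble::tibble(region_id = sites$region_id),
      tibble::as_tibble(counts * read_length))

    blocks_tbl <- if (n_sites > 0) {
      tibble::tibble(site_id = sites$region_id, block = block) |>
        dplyr::group_by(.data$block) |>
        dplyr::summarise(site_ids = list(.data$site_id), .groups = "drop") |>
        dplyr::mutate(block_id = sprintf("blk_%05d", .data$block)) |>
        dplyr::select("block_id", "site_ids")
    } else {
      tibble::tibble(block_id = character(), site_ids = list())
    }
    truth <- tibble::tibble(
      block_id = sprintf("blk_%05d", planted),
      site_ids = blocks_tbl$site_ids[match(sprintf("blk_%05d", planted),
                                           blocks_tbl$block_id)],
      direction = direction,
      effect = ifelse(direction == "hyper", effect, 1 / effect)
    )
    out <- list(profiles = profiles, samples = samples, truth = truth,
                blocks = blocks_tbl)

    if (output == "reads") {
      counts_tbl <- dplyr::bind_cols(
        tibble::tibble(region_id = sites$region_id),
        tibble::as_tibble(counts))
      long <- tidyr::pivot_longer(counts_tbl, -"region_id",
                                  names_to = "sample_id",
                                  values_to = "count")
      long <- long[long$count > 0, ]
      site_row <- match(long$region_id, sites$region_id)
      reads <- purrr::pmap(
        list(sites$chrom[site_row], sites$start[site_row],
             long$count, long$sample_id),
        function(ch, p, k, s) {
          # each read covers its 1-bp site by exactly one base
          offs <- sample.int(read_length, k, replace = TRUE) - 1
          tibble::tibble(chrom = ch, start = p - offs,
                         end = p - offs + read_length, sample_id = s)
        })
      out$reads <- dplyr::bind_rows(reads)
    }
    out
  })
}

#' Simulate a unit-level intensity matrix with planted differential units
#'
#' Fast path for statistical calibration: methylation units are generated
#' directly (member-site counts drawn Poisson, unit weight proportional to
#' site count), per-unit read counts follow the noise family, and intensity
#' is `count * read_length` bases. A fraction of units is planted
#' differential at the given fold, split evenly between hyper- and
#' hypomethylation (case mean multiplied or divided by `effect`).
#'
#' @param n_units Number of methylation units.
#' @param samples_per_group Replicates per group (default 3).
#' @param depth Mean reads per unit of average size (default 200).
#' @param dispersion Negative-binomial dispersion (default 0.1).
#' @param frac_planted Fraction of units planted (default 0).
#' @param effect Multiplicative fold for planted units (default 4).
#' @param mean_sites Poisson mean for member-site count, shifted by 1
#'   (default 4, so units average 5 sites).
#' @param noise `"nb"` or `"poisson"`.
#' @param read_length Bases per read (default 36).
#' @param seed RNG seed.
#' @return A list: `mat` (wide intensity tibble), `regions` (unit tibble
#'   with `region_id`, `role = "unit"`, `n_sites`), `samples`, `truth`
#'   (tibble `region_id`, `direction`, `effect`).
#' @export
simulate_unit_matrix <- function(n_units, samples_per_group = 3, depth = 200,
                                 dispersion = 0.1, frac_planted = 0,
                                 effect = 4, mean_sites = 4,
                                 noise = c("nb", "poisson"),
                                 read_length = 36, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(n_units >= 1, frac_planted >= 0, frac_planted < 1, effect > 0)
  samples <- tibble::tibble(
    sample_id = c(paste0("case_", seq_len(samples_per_group)),
                  paste0("ctrl_", seq_len(samples_per_group))),
    group = rep(c("case", "control"), each = samples_per_group)
  )
  with_rng(seed, {
    n_sites <- 1 + stats::rpois(n_units, mean_sites)
    weight <- n_sites / (1 + mean_sites)
    mu <- depth * weight

    planted <- sort(sample.int(n_units, size = round(frac_planted * n_units)))
    direction <- rep(c("hyper", "hypo"), length.out = length(planted))
    eff <- rep(1, n_units)
    eff[planted] <- ifelse(direction == "hyper", effect, 1 / effect)

    n_samp <- nrow(samples)
    is_case <- samples$group == "case"
    mu_mat <- matrix(mu, n_units, n_samp)
    mu_mat[, is_case] <- mu_mat[, is_case] * eff
    counts <- if (noise == "poisson") {
      matrix(stats::rpois(length(mu_mat), mu_mat), n_units, n_samp)
    } else {
      matrix(stats::rnbinom(length(mu_mat), mu = mu_mat,
                            size = 1 / dispersion), n_units, n_samp)
    }
    colnames(counts) <- samples$sample_id
    region_id <- sprintf("unit_%05d", seq_len(n_units))

    list(
      mat = dplyr::bind_cols(tibble::tibble(region_id = region_id),
                             tibble::as_tibble(counts * read_length)),
      regions = tibble::tibble(region_id = region_id, role = "unit",
                               n_sites = n_sites),
      samples = samples,
      truth = tibble::tibble(region_id = region_id[planted],
                             direction = direction,
                             effect = eff[planted])
    )
  })
}

#' Simulate a small-RNA count table with planted fold-changes
#'
#' Negative-binomial counts per feature per sample; a fraction of features
#' is planted with a multiplicative fold on the case mean (up/down in equal
#' shares). Subtype labels are assigned by the configured proportions;
#' defaults mirror a sperm library (tRF-dominant, then miRNA, then piRNA).
#'
#' @param n_features Number of small-RNA features (default 500).
#' @param samples_per_group Replicates per group (default 4).
#' @param mean_count Mean baseline count (default 200).
#' @param dispersion Negative-binomial dispersion (default 0.1).
#' @param frac_planted Fraction planted differential (default 0).
#' @param effect Multiplicative fold for planted features (default 4).
#' @param subtype_props Named numeric vector of subtype proportions
#'   (default `c(tRF = 0.45, miRNA = 0.3, piRNA = 0.15, rRNA = 0.05,
#'   other = 0.05)`).
#' @param seed RNG seed.
#' @return A list: `counts` (wide tibble), `samples`, `subtypes`, `truth`
#'   (tibble `feature_id`, `direction` in up/down, `effect`).
#' @export
simulate_smallrna <- function(n_features = 500, samples_per_group = 4,
                              mean_count = 200, dispersion = 0.1,
                              frac_planted = 0, effect = 4,
                              subtype_props = c(tRF = 0.45, miRNA = 0.3,
                                                piRNA = 0.15, rRNA = 0.05,
                                                other = 0.05),
                              seed = 1) {
  stopifnot(n_features >= 1, frac_planted >= 0, frac_planted < 1,
            abs(sum(subtype_props) - 1) < 1e-8)
  samples <- tibble::tibble(
    sample_id = c(paste0("case_", seq_len(samples_per_group)),
                  paste0("ctrl_", seq_len(samples_per_group))),
    group = rep(c("case", "control"), each = samples_per_group)
  )
  with_rng(seed, {
    feature_id <- sprintf("sRNA_%05d", seq_len(n_features))
    subtype <- sample(names(subtype_props), n_features, replace = TRUE,
                      prob = subtype_props)
    base <- mean_count * stats::rlnorm(n_features, 0, 1)

    planted <- sort(sample.int(n_features,
                               size = round(frac_planted * n_features)))
    direction <- rep(c("up", "down"), length.out = length(planted))
    eff <- rep(1, n_features)
    eff[planted] <- ifelse(direction == "up", effect, 1 / effect)

    n_samp <- nrow(samples)
    is_case <- samples$group == "case"
    mu <- matrix(base, n_features, n_samp)
    mu[, is_case] <- mu[, is_case] * eff
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / dispersion),
                     n_features, n_samp)
    colnames(counts) <- samples$sample_id

    list(
      counts = dplyr::bind_cols(tibble::tibble(feature_id = feature_id),
                                tibble::as_tibble(counts)),
      samples = samples,
      subtypes = tibble::tibble(feature_id = feature_id, subtype = subtype),
      truth = tibble::tibble(feature_id = feature_id[planted],
                             direction = direction, effect = eff[planted])
    )
  })
}
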