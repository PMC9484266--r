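## Synthetic cohort generator. Emulates the statistical structure of the
## study design — accessibility-defined regulatory regions, array probes
## with context bias, bulk methylomes of healthy epidermis and two tumor
## subclasses, sparse single-cell methylomes, clock CpGs and
## deconvolution references — with known ground truth, so that every
## analysis stage can be validated without external data.

#' Configuration for the synthetic-data generator
#'
#' Defaults reproduce the scale of the emulated study: 12 healthy, 22
#' EpSC-like and 33 keratinocyte-like samples; 914 regions accessible
#' only in undifferentiated keratinocytes (UK) and 864 accessible only
#' in differentiated keratinocytes (DK); mean probe counts of ~2,925
#' (UK) and ~1,426 (DK); 554 single cells at ~1% EpSC prevalence with
#' mean CpG coverage 0.85% (range 0.14--6.88%); stem-cell division
#' rates of 10.35 (healthy), 25 (EpSC-like) and 39.7
#' (keratinocyte-like) divisions per stem cell and year.
#'
#' @param seed Integer seed; all generators are deterministic given the
#'   config.
#' @param n_healthy,n_tumor_epsc,n_tumor_ker Bulk sample counts.
#' @param n_uk_regions,n_dk_regions Region counts per class.
#' @param uk_probe_rate,dk_probe_rate Mean probes per region (Poisson).
#' @param n_background_probes Probes outside any region; with the region
#'   probes this sets a CpG universe of ~50,000 sites.
#' @param beta_means 4x3 matrix of group mean beta, rows
#'   `UK, DK, background, marker`, columns `healthy, ker, epsc`.
#'   Healthy and keratinocyte-like tumors share means; EpSC-like tumors
#'   are hypomethylated at UK regions, hypermethylated at DK regions and
#'   at the planted microRNA-promoter marker blocks.
#' @param beta_precision Concentration of the beta noise distribution.
#' @param background_modes,background_mode_probs Baseline methylation of
#'   probes outside regulatory regions: each background probe draws a
#'   per-probe mean from this mixture, shared by all sample classes and
#'   cell types, reproducing the bimodal beta distribution of array
#'   methylomes (stably unmethylated islands, stably methylated bulk
#'   genome, a minority of intermediate CpGs).
#' @param enhancer_bg_fraction Fraction of background probes that are
#'   genome-wide strong-enhancer CpGs (`enhancer` row of `beta_means`):
#'   differentiation remodels enhancer methylation well beyond the
#'   differentially accessible peak set, and this component carries that
#'   genome-wide signal (hypomethylated in differentiated keratinocytes
#'   and their tumors, hypermethylated in EpSC-like samples and cells).
#' @param n_cells,epsc_cell_fraction Single-cell count and EpSC
#'   prevalence.
#' @param coverage_min,coverage_max,coverage_meanlog,coverage_sdlog
#'   Per-cell CpG coverage: log-normal, clipped to the stated range.
#' @param clock_n_cpgs,clock_delta_range,clock_p_range,clock_noise_sd
#'   Clock-CpG panel size, ground-state and gain-rate ranges, and the
#'   bounded Gaussian noise added to clock beta values.
#' @param clock_rates Divisions per stem cell and year per sample class.
#' @param clock_age_range Chronological ages drawn uniformly.
#' @param deconv_cell_types,deconv_markers_per_type,deconv_n_bulk,
#'   deconv_noise_sd Deconvolution reference structure and mixture count.
#' @param atac_cells_per_cluster,atac_n_null_regions,atac_fold,
#'   atac_base_rate,atac_nb_size Accessibility count model: negative
#'   binomial with a `atac_fold` rate elevation of UK regions in
#'   undifferentiated cells and DK regions in differentiated cells.
#' @param uk_region_length,dk_region_length Region lengths in bp; UK
#'   peaks are longer, which is why they capture more probes.
#' @param n_chroms,chrom_length Synthetic genome layout.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_healthy = 12L, n_tumor_epsc = 22L, n_tumor_ker = 33L,
                         n_uk_regions = 914L, n_dk_regions = 864L,
                         uk_probe_rate = 2925 / 914, dk_probe_rate = 1426 / 864,
                         n_background_probes = 45600L,
                         beta_means = rbind(
                           UK         = c(healthy = 0.60, ker = 0.60, epsc = 0.20),
                           DK         = c(healthy = 0.25, ker = 0.25, epsc = 0.70),
                           background = c(healthy = 0.50, ker = 0.50, epsc = 0.50),
                           marker     = c(healthy = 0.15, ker = 0.15, epsc = 0.75),
                           enhancer   = c(healthy = 0.25, ker = 0.25, epsc = 0.80)),
                         beta_precision = 30,
                         background_modes = c(0.10, 0.50, 0.85),
                         background_mode_probs = c(0.45, 0.10, 0.45),
                         enhancer_bg_fraction = 0.10,
                         n_cells = 554L, epsc_cell_fraction = 0.01,
                         coverage_min = 0.0014, coverage_max = 0.0688,
                         coverage_meanlog = log(0.0072), coverage_sdlog = 0.6,
                         clock_n_cpgs = 500L,
                         clock_delta_range = c(0, 0.1),
                         clock_p_range = c(1e-4, 5e-3),
                         clock_noise_sd = 0.02,
                         clock_rates = c(healthy = 10.35, epsc = 25, ker = 39.7),
                         clock_age_range = c(40, 80),
                         deconv_cell_types = c("Basal1", "Spinous", "Granular"),
                         deconv_markers_per_type = 20L,
                         deconv_n_bulk = 50L,
                         deconv_noise_sd = 0.01,
                         atac_cells_per_cluster = 200L,
                         atac_n_null_regions = 500L,
                         atac_fold = 4,
                         atac_base_rate = 0.5,
                         atac_nb_size = 10,
                         uk_region_length = 501L, dk_region_length = 301L,
                         n_chroms = 22L, chrom_length = 5e6) {
  cfg <- as.list(environment())
  stopifnot(cfg$seed == as.integer(cfg$seed),
            cfg$n_healthy >= 0, cfg$n_tumor_epsc >= 0, cfg$n_tumor_ker >= 0,
            all(beta_means > 0 & beta_means < 1),
            coverage_min > 0, coverage_max <= 1, coverage_min <= coverage_max,
            epsc_cell_fraction >= 0, epsc_cell_fraction <= 1,
            beta_precision > 0)
  class(cfg) <- "synth_config"
  cfg
}

## Mean-parameterized beta draw with concentration phi; respects (0,1)
## support by construction, no post-hoc clipping.
rbeta_mean <- function(n, mean, phi) {
  rbeta(n, shape1 = mean * phi, shape2 = (1 - mean) * phi)
}

#' Generate regulatory regions and a probe manifest
#'
#' Lays out non-overlapping UK and DK regions (plus two
#' microRNA-promoter marker blocks) on a synthetic genome, places
#' Poisson numbers of probes in each region, and adds background probes
#' outside all regions. UK-region probes are biased toward
#' promoter-associated CpG islands, DK-region probes toward OpenSea /
#' gene-body contexts, mirroring the context split observed between the
#' two accessibility classes. A small fraction of background probes sit
#' on sex chromosomes or carry SNP/cross-reactive flags so that probe
#' filtering is exercised.
#'
#' @param cfg A [synth_config()].
#' @return List with `regions` ([region_set()]), `manifest`
#'   ([probe_manifest()], with a `probe_class` attribute giving each
#'   probe's generating class), and `truth` (per-probe class, marker
#'   probe sets).
#' @export
generate_regions_and_manifest <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 11L)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))

  n_uk <- cfg$n_uk_regions
  n_dk <- cfg$n_dk_regions
  marker_genes <- c("MIR200C141", "MIR205")
  n_reg <- n_uk + n_dk + length(marker_genes)

  ## sequential slots with 4 kb spacing guarantee disjoint regions
  slot <- sample.int(n_reg) - 1L
  reg_chrom <- chroms[slot %% cfg$n_chroms + 1L]
  reg_start <- 1000L + (slot %/% cfg$n_chroms) * 4000L
  cls <- c(rep("UK", n_uk), rep("DK", n_dk), rep("marker", 2))
  len <- c(rep(cfg$uk_region_length, n_uk), rep(cfg$dk_region_length, n_dk),
           rep(501L, 2))
  reg_end <- reg_start + len

  region_idx <- which(cls != "marker")
  regions <- region_set(
    region_id = sprintf("%s_%04d", cls[region_idx],
                        unlist(lapply(c(n_uk, n_dk), seq_len))),
    chrom = reg_chrom[region_idx], start = reg_start[region_idx],
    end = reg_end[region_idx], region_class = cls[region_idx])

  ## probes inside regions
  n_probes_reg <- c(rpois(n_uk, cfg$uk_probe_rate),
                    rpois(n_dk, cfg$dk_probe_rate),
                    10L, 8L)  # marker promoter blocks
  probe_chrom <- rep(reg_chrom, n_probes_reg)
  probe_cls <- rep(cls, n_probes_reg)
  probe_gene <- rep(c(rep(NA_character_, n_uk + n_dk), marker_genes),
                    n_probes_reg)
  probe_pos <- unlist(lapply(seq_len(n_reg), function(i) {
    k <- n_probes_reg[i]
    if (k == 0) return(integer(0))
    sort(sample(seq.int(reg_start[i], reg_end[i] - 1L), k))
  }))

  island_probs <- list(
    UK = c(0.65, 0.15, 0.05, 0.15),
    DK = c(0.10, 0.10, 0.10, 0.70),
    marker = c(1, 0, 0, 0),
    enhancer = c(0.05, 0.10, 0.15, 0.70),
    background = c(0.25, 0.25, 0.25, 0.25))
  draw_island <- function(cls_vec) {
    out <- character(length(cls_vec))
    for (cl in unique(cls_vec)) {
      idx <- cls_vec == cl
      out[idx] <- sample(ISLAND_RELATIONS, sum(idx), replace = TRUE,
                         prob = island_probs[[cl]])
    }
    out
  }
  promoter_ctx <- c("TSS200", "TSS1500", "FirstExon", "UTR5")
  draw_generegion <- function(cls_vec) {
    out <- character(length(cls_vec))
    for (i in seq_along(cls_vec)) {
      out[i] <- switch(cls_vec[i],
        UK = if (runif(1) < 0.8) sample(promoter_ctx, 1) else "Body",
        DK = sample(c("Body", "Intergenic"), 1, prob = c(0.3, 0.7)),
        marker = "TSS200",
        enhancer = sample(c("Body", "Intergenic"), 1, prob = c(0.2, 0.8)),
        background = sample(GENE_REGIONS, 1))
    }
    out
  }

  ## background probes: a genome-wide enhancer-like subset (its own zone,
  ## so the synthetic segmentation can label it state 4/5) plus plain
  ## background outside the region zone
  n_bg <- cfg$n_background_probes
  n_enh <- round(cfg$enhancer_bg_fraction * n_bg)
  n_oth <- n_bg - n_enh
  enh_chrom <- sample(chroms, n_enh, replace = TRUE)
  enh_pos <- 330000L + sample.int(69000L, n_enh, replace = TRUE)
  n_sex <- round(0.02 * n_oth)
  oth_chrom <- c(sample(chroms, n_oth - n_sex, replace = TRUE),
                 sample(SEX_CHROMS, n_sex, replace = TRUE))
  oth_pos <- 400000L + sample.int(as.integer(cfg$chrom_length - 4e5), n_oth,
                                  replace = TRUE)
  oth_snp <- runif(n_oth) < 0.01
  oth_xr <- runif(n_oth) < 0.01

  all_chrom <- c(probe_chrom, enh_chrom, oth_chrom)
  all_pos <- c(probe_pos, enh_pos, oth_pos)
  all_cls <- c(probe_cls, rep("enhancer", n_enh), rep("background", n_oth))
  all_gene <- c(probe_gene, rep(NA_character_, n_bg))
  n_tot <- length(all_pos)
  manifest <- probe_manifest(
    probe_id = sprintf("cg%07d", seq_len(n_tot)),
    chrom = all_chrom, pos = all_pos,
    island_relation = draw_island(all_cls),
    gene_regions = draw_generegion(all_cls),
    gene_symbol = all_gene,
    flag_snp = c(rep(FALSE, length(probe_pos) + n_enh), oth_snp),
    flag_crossreactive = c(rep(FALSE, length(probe_pos) + n_enh), oth_xr))
  attr(manifest, "probe_class") <- all_cls

  ## shared per-probe baseline for background probes (bimodal, identical
  ## across sample classes); signal probes use the class-mean table
  base_mean <- rep(NA_real_, n_tot)
  base_mean[all_cls == "background"] <- sample(
    cfg$background_modes, n_oth, replace = TRUE,
    prob = cfg$background_mode_probs)
  attr(manifest, "probe_base_mean") <- base_mean

  truth <- list(
    probe_class = setNames(all_cls, manifest$probe_id),
    probe_base_mean = setNames(base_mean, manifest$probe_id),
    marker_probes = split(manifest$probe_id[!is.na(all_gene)],
                          all_gene[!is.na(all_gene)]),
    n_probes_uk = sum(all_cls == "UK"),
    n_probes_dk = sum(all_cls == "DK"))
  list(regions = regions, manifest = manifest, truth = truth)
}

## per-probe class -> per-sample-type mean lookup; background probes use
## their shared per-probe baseline when available
probe_mean_matrix <- function(cfg, probe_class, sample_type,
                              base_mean = NULL) {
  m <- cfg$beta_means[cbind(match(probe_class,
                                  c("UK", "DK", "background", "marker",
                                    "enhancer")),
                            match(sample_type,
                                  c("healthy", "ker", "epsc")))]
  if (!is.null(base_mean)) {
    use <- !is.na(base_mean)
    m[use] <- base_mean[use]
  }
  m
}

#' Generate a bulk methylome cohort
#'
#' Draws beta values for the healthy / EpSC-like / keratinocyte-like
#' cohort from mean-parameterized beta distributions. Healthy and
#' keratinocyte-like samples share group means at both region classes;
#' EpSC-like samples are hypomethylated at UK regions (whose chromatin
#' is open, hence unmethylated, in their cell of origin),
#' hypermethylated at DK regions (enhancer hypermethylation relative to
#' differentiated cells), and hypermethylated at the planted
#' microRNA-promoter marker blocks.
#'
#' @param cfg A [synth_config()].
#' @param regions,manifest Output of [generate_regions_and_manifest()].
#' @return List with `beta` ([beta_matrix()]) and `truth` (per-sample
#'   true subclass, per-probe class).
#' @export
generate_bulk <- function(cfg, regions, manifest) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 23L)
  probe_class <- attr(manifest, "probe_class")
  if (is.null(probe_class)) probe_class <- probe_class_from_regions(manifest, regions)
  base_mean <- attr(manifest, "probe_base_mean")

  n_t <- cfg$n_tumor_epsc + cfg$n_tumor_ker
  tumor_type <- sample(c(rep("epsc", cfg$n_tumor_epsc),
                         rep("ker", cfg$n_tumor_ker)))
  sample_type <- c(rep("healthy", cfg$n_healthy), tumor_type)
  sample_ids <- c(sprintf("H%02d", seq_len(cfg$n_healthy)),
                  sprintf("T%02d", seq_len(n_t)))
  n_ak <- min(20L, n_t)
  group <- c(rep("Healthy", cfg$n_healthy),
             sample(c(rep("AK", n_ak), rep("cSCC", n_t - n_ak))))

  P <- nrow(manifest)
  vals <- matrix(NA_real_, P, length(sample_ids),
                 dimnames = list(manifest$probe_id, sample_ids))
  for (j in seq_along(sample_ids)) {
    m <- probe_mean_matrix(cfg, probe_class, sample_type[j], base_mean)
    vals[, j] <- rbeta_mean(P, m, cfg$beta_precision)
  }
  truth <- list(
    true_subclass = setNames(
      c(rep("Healthy", cfg$n_healthy),
        ifelse(tumor_type == "epsc", "EpSC-like", "Keratinocyte-like")),
      sample_ids),
    sample_type = setNames(sample_type, sample_ids),
    probe_class = setNames(probe_class, manifest$probe_id))
  list(beta = beta_matrix(vals, group), truth = truth)
}

probe_class_from_regions <- function(manifest, regions) {
  cls <- rep("background", nrow(manifest))
  hits <- GenomicRanges::findOverlaps(manifest_granges(manifest),
                                      regions_granges(regions))
  cls[S4Vectors::queryHits(hits)] <-
    as.character(regions$region_class[S4Vectors::subjectHits(hits)])
  cls[!is.na(manifest$gene_symbol)] <- "marker"
  cls
}

#' Generate sparse single-cell methylomes
#'
#' Each cell is an EpSC with probability `epsc_cell_fraction`
#' (differentiated keratinocyte otherwise). Its CpG coverage fraction is
#' drawn from a clipped log-normal; covered positions are sampled
#' uniformly from the probe universe and each call is Bernoulli with the
#' cell-type-specific mean of that probe's region class.
#'
#' @param cfg A [synth_config()].
#' @param manifest Manifest from [generate_regions_and_manifest()] (its
#'   probe positions are the CpG universe).
#' @param regions Regions (used to derive probe classes when the
#'   manifest lacks the generator's `probe_class` attribute).
#' @return List with `profiles` (list of [scmeth_profile()]) and `truth`
#'   (per-cell true type, per-cell coverage).
#' @export
generate_cells <- function(cfg, manifest, regions = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 37L)
  probe_class <- attr(manifest, "probe_class")
  if (is.null(probe_class)) {
    if (is.null(regions)) stop("regions required when manifest lacks probe_class")
    probe_class <- probe_class_from_regions(manifest, regions)
  }
  base_mean <- attr(manifest, "probe_base_mean")
  P <- nrow(manifest)
  n <- cfg$n_cells
  cell_type <- ifelse(runif(n) < cfg$epsc_cell_fraction, "epsc", "ker")
  coverage <- pmin(pmax(rlnorm(n, cfg$coverage_meanlog, cfg$coverage_sdlog),
                        cfg$coverage_min), cfg$coverage_max)
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    k <- max(1L, round(coverage[i] * P))
    idx <- sort(sample.int(P, k))
    m <- probe_mean_matrix(cfg, probe_class[idx], cell_type[i],
                           if (!is.null(base_mean)) base_mean[idx])
    call <- rbinom(k, 1L, m)
    cid <- sprintf("cell%03d", i)
    profiles[[i]] <- scmeth_profile(
      cid, manifest$chrom[idx], manifest$pos[idx], call,
      n_reads = 100000L + round(coverage[i] * 5e7), universe_size = P)
  }
  names(profiles) <- vapply(profiles, `[[`, "", "cell_id")
  truth <- list(cell_type = setNames(ifelse(cell_type == "epsc", "EpSC",
                                            "Keratinocyte"),
                                     names(profiles)),
                coverage = setNames(coverage, names(profiles)))
  list(profiles = profiles, truth = truth)
}

#' Generate clock-CpG methylomes with known mitotic ages
#'
#' Draws a clock panel (ground states `delta`, gain rates `p`), assigns
#' each sample a chronological age and a class-specific stem-cell
#' division rate, and simulates beta values under the per-division gain
#' model `beta = delta + (1-delta) * (1 - (1-p)^T)` plus bounded
#' Gaussian noise, where `T = rate x age` is the cumulative division
#' count.
#'
#' @param cfg A [synth_config()].
#' @return List with `beta` ([beta_matrix()] over clock CpGs), `model`
#'   ([clock_model()]), `ages` (named vector), and `truth` (true `T`,
#'   class, rates).
#' @export
generate_clock_samples <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 41L)
  ncl <- cfg$clock_n_cpgs
  model <- clock_model(
    sprintf("clk%04d", seq_len(ncl)),
    delta = runif(ncl, cfg$clock_delta_range[1], cfg$clock_delta_range[2]),
    p = runif(ncl, cfg$clock_p_range[1], cfg$clock_p_range[2]))
  n_per <- c(healthy = cfg$n_healthy, epsc = cfg$n_tumor_epsc,
             ker = cfg$n_tumor_ker)
  sample_type <- rep(names(n_per), n_per)
  ids <- sprintf("C%02d", seq_along(sample_type))
  ages <- setNames(runif(length(ids), cfg$clock_age_range[1],
                         cfg$clock_age_range[2]), ids)
  true_T <- setNames(cfg$clock_rates[sample_type] * ages, ids)
  vals <- sapply(seq_along(ids), function(j) {
    mu <- model$delta + (1 - model$delta) * (1 - (1 - model$p)^true_T[j])
    pmin(pmax(mu + rnorm(ncl, 0, cfg$clock_noise_sd), 0), 1)
  })
  dimnames(vals) <- list(model$cpg_id, ids)
  group <- c(healthy = "Healthy", epsc = "cSCC", ker = "cSCC")[sample_type]
  list(beta = beta_matrix(vals, group), model = model, ages = ages,
       truth = list(true_T = true_T,
                    sample_type = setNames(sample_type, ids),
                    rates = cfg$clock_rates))
}

#' Generate deconvolution references and mixed bulks
#'
#' Builds a marker-gene expression reference over the keratinocyte
#' differentiation trajectory (each marker high in exactly one cell
#' type), a paired promoter-methylation table that is anti-correlated
#' with expression (plus a few wrong-sign genes that the imputation
#' filter must drop), and bulk promoter methylomes mixed from the
#' methylation reference with Dirichlet ground-truth fractions.
#'
#' @param cfg A [synth_config()].
#' @return List with `expression` (gene x cell-type means), `paired_meth`
#'   (gene x cell-type promoter methylation), `bulk` (marker x sample
#'   beta matrix), and `truth` (`fractions` samples x types,
#'   `n_anticorrelated`).
#' @export
generate_deconv_inputs <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 53L)
  types <- cfg$deconv_cell_types
  K <- length(types)
  mk <- cfg$deconv_markers_per_type
  marker_genes <- unlist(lapply(types, function(t) sprintf("%s_mk%02d", t, seq_len(mk))))
  marker_type <- rep(types, each = mk)

  expr <- matrix(0.5, length(marker_genes), K,
                 dimnames = list(marker_genes, types))
  expr[cbind(seq_along(marker_genes), match(marker_type, types))] <- 10
  ## housekeeping genes: expressed everywhere, must not become markers
  hk <- matrix(5, 10, K, dimnames = list(sprintf("HK%02d", 1:10), types))
  expr <- rbind(expr, hk)

  meth <- matrix(NA_real_, length(marker_genes), K,
                 dimnames = list(marker_genes, types))
  jit <- function(n, m) pmin(pmax(m + runif(n, -0.05, 0.05), 0), 1)
  for (i in seq_along(marker_genes)) {
    meth[i, ] <- jit(K, 0.8)
    meth[i, marker_type[i]] <- jit(1, 0.1)
  }
  ## wrong-sign genes: methylated where expressed; imputation drops them
  n_wrong <- 3L
  wrong_ids <- sample(seq_along(marker_genes), n_wrong)
  for (i in wrong_ids) {
    meth[i, ] <- jit(K, 0.1)
    meth[i, marker_type[i]] <- jit(1, 0.8)
  }

  nb <- cfg$deconv_n_bulk
  w <- matrix(rgamma(nb * K, shape = 1), nb, K)
  w <- w / rowSums(w)
  dimnames(w) <- list(sprintf("B%02d", seq_len(nb)), types)
  keep <- setdiff(seq_along(marker_genes), wrong_ids)
  bulk <- meth[keep, , drop = FALSE] %*% t(w) +
    matrix(rnorm(length(keep) * nb, 0, cfg$deconv_noise_sd), length(keep), nb)
  bulk <- pmin(pmax(bulk, 0), 1)
  list(expression = expr, paired_meth = meth,
       bulk = beta_matrix(bulk, "Other"),
       truth = list(fractions = w,
                    n_anticorrelated = length(marker_genes) - n_wrong,
                    marker_type = setNames(marker_type, marker_genes)))
}

#' Generate a region-by-cell accessibility count matrix
#'
#' Negative-binomial insertion counts for two keratinocyte clusters
#' (undifferentiated and differentiated): UK regions have their rate
#' multiplied by `atac_fold` in undifferentiated cells, DK regions in
#' differentiated cells, and appended null regions have equal rates.
#'
#' @param cfg A [synth_config()].
#' @param regions A [region_set()] (the planted signal regions).
#' @return List with `counts` (region x cell integer matrix), `labels`
#'   (factor per cell, levels `undiff`, `diff`), and `truth` (per-region
#'   planted class, `NS` for nulls).
#' @export
generate_atac <- function(cfg, regions) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 67L)
  ncc <- cfg$atac_cells_per_cluster
  if (ncc < 1) stop("each cluster needs at least one cell")
  reg_class <- c(as.character(regions$region_class),
                 rep("NS", cfg$atac_n_null_regions))
  reg_ids <- c(regions$region_id,
               sprintf("null_%04d", seq_len(cfg$atac_n_null_regions)))
  labels <- factor(rep(c("undiff", "diff"), each = ncc),
                   levels = c("undiff", "diff"))
  cell_ids <- sprintf("atac%04d", seq_along(labels))
  base <- cfg$atac_base_rate
  rate_undiff <- ifelse(reg_class == "UK", base * cfg$atac_fold,
                        ifelse(reg_class == "DK", base, base * 2))
  rate_diff <- ifelse(reg_class == "DK", base * cfg$atac_fold,
                      ifelse(reg_class == "UK", base, base * 2))
  R <- length(reg_ids)
  counts <- cbind(
    matrix(rnbinom(R * ncc, size = cfg$atac_nb_size, mu = rate_undiff),
           R, ncc),
    matrix(rnbinom(R * ncc, size = cfg$atac_nb_size, mu = rate_diff),
           R, ncc))
  dimnames(counts) <- list(reg_ids, cell_ids)
  list(counts = counts, labels = setNames(labels, cell_ids),
       truth = list(region_class = setNames(reg_class, reg_ids)))
}

#' Generate a chromatin-state segmentation matched to the synthetic genome
#'
#' A convenience segmentation for state-level summaries: UK regions are
#' labeled active promoters (state 1), DK regions and the genome-wide
#' enhancer-probe zone strong enhancers (states 4/5), and the remaining
#' genome heterochromatin/low signal (state 13).
#'
#' @param cfg A [synth_config()].
#' @param regions A [region_set()] from [generate_regions_and_manifest()].
#' @return A [segmentation()].
#' @export
generate_segmentation <- function(cfg, regions) {
  set.seed(cfg$seed + 71L)
  state <- ifelse(regions$region_class == "UK", 1L,
                  sample(c(4L, 5L), nrow(regions), replace = TRUE))
  seg <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end, state = state,
                    stringsAsFactors = FALSE)
  ## enhancer-probe zone as strong-enhancer states, the rest of each
  ## chromosome as state-13 blocks
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  enh <- data.frame(chrom = rep(chroms, 2),
                    start = rep(c(330000L, 365000L), each = cfg$n_chroms),
                    end = rep(c(365000L, 399000L), each = cfg$n_chroms),
                    state = rep(c(4L, 5L), each = cfg$n_chroms))
  rest <- data.frame(chrom = chroms, start = 400000L,
                     end = as.integer(cfg$chrom_length), state = 13L)
  all <- rbind(seg, enh, rest)
  segmentation(all$chrom, all$start, all$end, all$state)
}
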