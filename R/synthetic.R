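#' Configuration for the synthetic metastudy generator
#'
#' Defines a multi-experiment gut-microbiota metastudy with known planted
#' structure: a small set of high-prevalence, high-abundance core classes
#' (one of which, the indicator class, is enriched under pollution), a set
#' of intermediate transient classes, and a remainder of rare classes.
#' Counts are drawn Dirichlet-multinomial around class-level expected
#' compositions with per-experiment log-normal batch effects, the standard
#' overdispersed compositional model for 16S count data.
#'
#' Presence is hierarchical: a class is first present or absent in an
#' entire experiment (studies differ in what they detect at all), then
#' present or absent per sample. Core classes are ubiquitous at both
#' levels; transient classes occur in every experiment but not every
#' sample; rare classes are missing from most experiments.
#'
#' Default shares are calibrated so the expected realized abundance of the
#' core / transient / rare fractions is roughly 51 / 36 / 14 percent of
#' reads, and the default study shape (17 experiments, 12 samples per
#' group, reads rarefied downstream to 2000) mirrors a ~400-sample
#' soil-invertebrate gut metastudy.
#'
#' @param n_experiments number of independent experiments.
#' @param samples_per_experiment samples per group (Control / Pollution)
#'   within each experiment.
#' @param library_size reads per sample before rarefaction.
#' @param n_classes total number of bacterial classes.
#' @param genera_per_class genera simulated within each class.
#' @param core_classes,transient_classes integer ids of the planted core
#'   and transient classes (disjoint); remaining classes are rare.
#' @param indicator_class id of the pollution-responsive class; may
#'   coincide with a core class (the empirically relevant case).
#' @param pollution_fold_change multiplicative enrichment (>= 1) applied
#'   to indicator-class genera in Pollution samples before renormalization.
#' @param dispersion Dirichlet concentration scalar; larger = less
#'   overdispersion.
#' @param batch_sd log-scale standard deviation of per-experiment,
#'   per-class batch multipliers.
#' @param core_share,transient_share,rare_share nominal per-class
#'   abundance shares by category (internally normalized to sum to one
#'   over all classes).
#' @param class_shares optional numeric vector of length `n_classes`
#'   overriding the category-based shares.
#' @param presence_experiment,presence_sample named numeric vectors
#'   (`core`, `transient`, `rare`) of presence probabilities at the
#'   experiment and sample level.
#' @param seed integer seed; all randomness in the generator flows from it.
#' @return a `synth_config` list, validated.
#' @export
synth_config <- function(n_experiments = 17,
                         samples_per_experiment = 12,
                         library_size = 2500,
                         n_classes = 20,
                         genera_per_class = 3,
                         core_classes = 1:3,
                         transient_classes = 4:7,
                         indicator_class = 1,
                         pollution_fold_change = 2.5,
                         dispersion = 200,
                         batch_sd = 0.15,
                         core_share = 0.1689,
                         transient_share = 0.1114,
                         rare_share = 0.0301,
                         class_shares = NULL,
                         presence_experiment = c(core = 1, transient = 1,
                                                 rare = 0.4),
                         presence_sample = c(core = 1, transient = 0.8,
                                             rare = 0.85),
                         seed = 1) {
  stopifnot(n_experiments >= 1, samples_per_experiment >= 1,
            library_size >= 1, n_classes >= 1, genera_per_class >= 1,
            dispersion > 0, batch_sd >= 0)
  if (pollution_fold_change < 1) {
    stop("pollution_fold_change must be >= 1")
  }
  if (length(intersect(core_classes, transient_classes))) {
    stop("core and transient class ids must be disjoint")
  }
  if (!all(c(core_classes, transient_classes, indicator_class) %in%
           seq_len(n_classes))) {
    stop("class ids out of range")
  }
  category <- rep("rare", n_classes)
  category[core_classes] <- "core"
  category[transient_classes] <- "transient"
  if (is.null(class_shares)) {
    class_shares <- c(core = core_share, transient = transient_share,
                      rare = rare_share)[category]
  }
  stopifnot(length(class_shares) == n_classes, all(class_shares >= 0),
            sum(class_shares) > 0)
  class_shares <- class_shares / sum(class_shares)
  cfg <- list(n_experiments = n_experiments,
              samples_per_experiment = samples_per_experiment,
              library_size = library_size, n_classes = n_classes,
              genera_per_class = genera_per_class,
              core_classes = core_classes,
              transient_classes = transient_classes,
              indicator_class = indicator_class,
              pollution_fold_change = pollution_fold_change,
              dispersion = dispersion, batch_sd = batch_sd,
              class_shares = unname(class_shares),
              category = category,
              presence_experiment = presence_experiment,
              presence_sample = presence_sample,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  cfg
}

# class / genus labels and the planted lineage hierarchy
synth_taxonomy <- function(cfg) {
  K <- cfg$n_classes; G <- cfg$genera_per_class
  cls <- sprintf("C%02d", seq_len(K))
  phy <- sprintf("P%02d", (seq_len(K) - 1L) %/% 3L + 1L)
  rows <- do.call(rbind, lapply(seq_len(K), function(k) {
    data.frame(class_id = k,
               genus = sprintf("%s_g%d", cls[k], seq_len(G)),
               domain = "Bacteria", phylum = phy[k], class = cls[k],
               order = sprintf("O%02d", k),
               family = sprintf("F%02d_%d", k, (seq_len(G) - 1L) %/% 2L + 1L),
               stringsAsFactors = FALSE)
  }))
  lin <- rows[, c("domain", "phylum", "class", "order", "family")]
  lin$genus <- rows$genus
  data.frame(taxon_id = rows$genus,
             lineage = make_lineage(lin),
             class_id = rows$class_id,
             stringsAsFactors = FALSE)
}

#' Simulate a multi-experiment metastudy with planted structure
#'
#' Draws per-experiment samples x genus count tables around the class-level
#' expected composition in the configuration, applies per-experiment batch
#' effects, hierarchical presence/absence, and the pollution enrichment of
#' the indicator class, then packages everything with taxonomy and sample
#' metadata. Deterministic given `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list with `tables` (one [count_table()] per experiment),
#'   `taxonomy`, `sample_meta`, and `truth` (planted class categories,
#'   indicator genera, expected class shares).
#' @export
simulate_metastudy <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  K <- cfg$n_classes; G <- cfg$genera_per_class
  tax <- synth_taxonomy(cfg)
  cls <- sprintf("C%02d", seq_len(K))
  genus_class <- tax$class_id

  withr::with_seed(cfg$seed, {
    tables <- vector("list", cfg$n_experiments)
    metas <- vector("list", cfg$n_experiments)
    for (e in seq_len(cfg$n_experiments)) {
      batch <- exp(stats::rnorm(K, 0, cfg$batch_sd))
      z_exp <- stats::rbinom(K, 1, cfg$presence_experiment[cfg$category])
      n_s <- cfg$samples_per_experiment
      ids <- sprintf("E%02d_S%03d", e, seq_len(2 * n_s))
      groups <- rep(c("Control", "Pollution"), each = n_s)
      counts <- matrix(0L, nrow = 2 * n_s, ncol = K * G,
                       dimnames = list(ids, tax$taxon_id))
      for (i in seq_len(2 * n_s)) {
        y <- z_exp * stats::rbinom(K, 1, cfg$presence_sample[cfg$category])
        m <- cfg$class_shares * batch * y
        if (groups[i] == "Pollution") {
          m[cfg$indicator_class] <- m[cfg$indicator_class] *
            cfg$pollution_fold_change
        }
        if (sum(m) == 0) {  # pathological config: fall back to largest class
          m[which.max(cfg$class_shares)] <- 1
        }
        m <- m / sum(m)
        mg <- rep(m / G, each = G)
        w <- stats::rgamma(K * G, shape = cfg$dispersion * mg)
        if (sum(w) == 0) w[which.max(mg)] <- 1
        counts[i, ] <- stats::rmultinom(1, cfg$library_size, w / sum(w))
      }
      metas[[e]] <- data.frame(sample_id = ids,
                               experiment_id = sprintf("E%02d", e),
                               group = groups, host = "synthetic",
                               stringsAsFactors = FALSE)
      tables[[e]] <- count_table(counts, metas[[e]],
                                 tax[, c("taxon_id", "lineage")])
    }
  })
  truth <- list(
    class_category = stats::setNames(cfg$category, cls),
    indicator_class = cls[cfg$indicator_class],
    indicator_genera = tax$taxon_id[genus_class == cfg$indicator_class],
    class_shares = stats::setNames(cfg$class_shares, cls))
  list(tables = tables,
       taxonomy = tax[, c("taxon_id", "lineage")],
       sample_meta = do.call(rbind, metas),
       truth = truth)
}

#' Write a simulated metastudy to disk
#'
#' One count TSV per experiment plus taxonomy and metadata TSVs and the
#' configuration as YAML; the file layout [run_pipeline()] consumes.
#'
#' @param sim result of [simulate_metastudy()].
#' @param dir output directory (created if needed).
#' @param config the [synth_config()] used (serialized alongside).
#' @param biom also write each experiment as BIOM 1.0 (JSON).
#' @return invisibly, the vector of table paths.
#' @export
write_metastudy <- function(sim, dir, config = NULL, biom = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (t in sim$tables) {
    e <- t$sample_meta$experiment_id[1]
    p <- file.path(dir, paste0("counts_", e, ".tsv"))
    write_count_table(t, p, "tsv")
    if (biom) write_count_table(t, file.path(dir, paste0("counts_", e,
                                                         ".biom")), "biom")
    paths <- c(paths, p)
  }
  write_tsv(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_tsv(sim$sample_meta, file.path(dir, "metadata.tsv"))
  if (!is.null(config)) {
    cfg <- config
    class(cfg) <- NULL
    cfg$presence_experiment <- as.list(cfg$presence_experiment)
    cfg$presence_sample <- as.list(cfg$presence_sample)
    yaml::write_yaml(cfg, file.path(dir, "config.yml"))
  }
  invisible(paths)
}

#' Simulate an HT-qPCR chip with planted detections
#'
#' Emulates a resistance-gene chip: each gene is measured in
#' `n_bio x n_tech` wells. Planted detected genes amplify below the
#' cycle-31 threshold in every well; undetected genes either fail to
#' amplify (empty wells) or amplify too late or too inconsistently to
#' satisfy the 3 technical + 3 biological replicate rule. A 16S reference
#' gene (always strongly amplified) is appended for normalization.
#'
#' @param n_genes number of assay genes (ARGs).
#' @param n_bio,n_tech biological and technical replicates per gene.
#' @param detected_fraction fraction of genes planted as detected.
#' @param ct_threshold detection threshold cycle (default 31).
#' @param seed integer seed.
#' @return list with `ct` (long data.frame: `gene_id`, `gene_class`,
#'   `bio_rep`, `tech_rep`, `ct`; `NA` = no amplification) and
#'   `truth` (planted detected gene ids).
#' @export
simulate_ct_chip <- function(n_genes, n_bio = 3, n_tech = 3,
                             detected_fraction = 0.5, ct_threshold = 31,
                             seed = 1) {
  stopifnot(n_genes >= 1, n_bio >= 1, n_tech >= 1)
  if (detected_fraction < 0 || detected_fraction > 1) {
    stop("detected_fraction must be in [0, 1]")
  }
  genes <- sprintf("ARG%03d", seq_len(n_genes))
  withr::with_seed(seed, {
    n_det <- round(detected_fraction * n_genes)
    detected <- sort(sample(genes, n_det))
    rows <- list()
    for (g in genes) {
      is_det <- g %in% detected
      wells <- expand.grid(bio_rep = seq_len(n_bio),
                           tech_rep = seq_len(n_tech))
      if (is_det) {
        ct <- stats::runif(nrow(wells), 20, ct_threshold - 0.5)
      } else {
        # late amplification or dropout; never 3x3 below threshold
        ct <- ifelse(stats::runif(nrow(wells)) < 0.5, NA,
                     stats::runif(nrow(wells), ct_threshold, 40))
        lucky <- stats::runif(nrow(wells)) < 0.25
        ct[lucky] <- stats::runif(sum(lucky), 25, ct_threshold - 0.1)
        # knock out one technical well per biological replicate if the
        # stray early wells would otherwise satisfy the replicate rule
        ok_bio <- tapply(ct < ct_threshold & !is.na(ct), wells$bio_rep, sum)
        if (sum(ok_bio >= min(3, n_tech)) >= min(3, n_bio)) {
          for (b in seq_len(n_bio)) {
            idx <- which(wells$bio_rep == b)[1]
            ct[idx] <- NA
          }
        }
      }
      rows[[g]] <- data.frame(gene_id = g, gene_class = "ARG",
                              bio_rep = wells$bio_rep,
                              tech_rep = wells$tech_rep, ct = ct,
                              stringsAsFactors = FALSE)
    }
    ref <- expand.grid(bio_rep = seq_len(n_bio), tech_rep = seq_len(n_tech))
    rows[["16S"]] <- data.frame(gene_id = "16S", gene_class = "16S",
                                bio_rep = ref$bio_rep,
                                tech_rep = ref$tech_rep,
                                ct = stats::runif(nrow(ref), 12, 16),
                                stringsAsFactors = FALSE)
  })
  ct <- do.call(rbind, rows)
  rownames(ct) <- NULL
  list(ct = ct, truth = detected)
}

#' Simulate a per-sample resistance-gene burden driven by an ARB class
#'
#' Links community composition to the resistome: the total ARG abundance
#' of each sample is proportional to the relative abundance of a planted
#' antibiotic-resistant-bacteria (ARB) class plus log-normal noise, so
#' correlation screens can be validated against a known carrier.
#'
#' @param class_abund samples x classes matrix of relative abundances.
#' @param arb_class column name of the planted carrier class.
#' @param coef proportionality coefficient.
#' @param noise_sd log-scale noise standard deviation.
#' @param seed integer seed.
#' @return numeric vector of per-sample ARG abundance.
#' @export
simulate_arg_burden <- function(class_abund, arb_class, coef = 1,
                                noise_sd = 0.3, seed = 1) {
  m <- as.matrix(class_abund)
  if (!arb_class %in% colnames(m)) stop("unknown ARB class: ", arb_class)
  withr::with_seed(seed, {
    coef * m[, arb_class] * exp(stats::rnorm(nrow(m), 0, noise_sd))
  })
}

#' Simulate a concentric-ring locomotion assay
#'
#' Individuals are released at the center of a five-ring test map (outer
#' radii 5, 10, 15, 20, 30 cm) and counted per ring at each timepoint.
#' Each individual's ring at time `t` is `1 + min(4, Poisson(drift * t))`,
#' so `drift = 0` leaves everyone in the innermost ring and larger drift
#' pushes counts outward over time. Counts are conserved at every
#' timepoint.
#'
#' @param n_individuals individuals released (13 in the standard assay).
#' @param drift outward-movement rate per minute (>= 0).
#' @param timepoints observation times in minutes.
#' @param seed integer seed.
#' @return a locomotion table: 5 x length(timepoints) integer matrix with
#'   rows `A1`..`A5`, columns `t<minutes>`, and attributes `radii_cm` and
#'   `n_individuals`.
#' @export
simulate_locomotion <- function(n_individuals = 13, drift = 0.1,
                                timepoints = c(2, 4, 6, 8, 10), seed = 1) {
  if (drift < 0) stop("drift must be non-negative")
  stopifnot(n_individuals >= 1, length(timepoints) >= 1)
  out <- matrix(0L, nrow = 5, ncol = length(timepoints),
                dimnames = list(paste0("A", 1:5),
                                paste0("t", timepoints)))
  withr::with_seed(seed, {
    for (j in seq_along(timepoints)) {
      ring <- 1L + pmin(4L, stats::rpois(n_individuals,
                                         drift * timepoints[j]))
      out[, j] <- tabulate(ring, nbins = 5L)
    }
  })
  attr(out, "radii_cm") <- c(5, 10, 15, 20, 30)
  attr(out, "n_individuals") <- n_individuals
  out
}
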