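#' Generate a seeded synthetic microbiome study with planted contaminants
#'
#' Builds a study in which both classic contamination signatures hold by
#' construction, so score recovery is a fair test:
#' * biological samples draw high DNA concentrations and negative controls
#'   low ones (both log-normal), and sequencing depth is proportional to
#'   concentration — controls are low-biomass;
#' * each contaminant contributes an expected relative frequency
#'   proportional to `1 / concentration` (times a per-taxon level and
#'   log-normal noise), i.e. a roughly constant number of molecules per
#'   sample, and is therefore near-ubiquitous in controls;
#' * biological taxa follow a log-normal community, essentially absent from
#'   controls except for a small carry-over.
#'
#' Counts are drawn multinomially per sample at the concentration-scaled
#' depth; a small unassigned count per sample exercises the
#' assigned+unassigned totals. A two-rank toy taxonomy (genus > species) is
#' attached, with contaminants spread across genera.
#'
#' @param n_bio number of biological samples
#' @param n_ctrl number of negative-control samples
#' @param n_obs number of observations (species-level taxa)
#' @param n_contam number of planted contaminants (`<= n_obs`)
#' @param seed RNG seed; all randomness flows through it
#' @param noise_sd log-normal noise (log scale sd) on contaminant
#'   frequencies
#' @param depth_mean expected sequencing depth of a biological sample at the
#'   reference concentration
#' @return a `synthetic_study`: list with `table` ([count_table]),
#'   `metadata` (`sample_metadata` with fields `sample_type`, `dna_conc`,
#'   `batch`), `controls` (`control_groups` with group
#'   `"negative_controls"`), `taxonomy` ([taxonomy_db]), `truth` (character
#'   vector of contaminant observation ids) and `params`
#' @export
generate_study <- function(n_bio = 80, n_ctrl = 16, n_obs = 100,
                           n_contam = 20, seed = 7, noise_sd = 0.3,
                           depth_mean = 20000) {
  if (n_bio < 1 || n_ctrl < 1 || n_obs < 1 || n_contam < 0 ||
      n_contam > n_obs)
    kstop("generate_study", "invalid sizes (need n_contam <= n_obs, all >= 1)")
  with_seed(seed, {
    obs <- sprintf("sp%03d", seq_len(n_obs))
    contam <- sort(sample(obs, n_contam))
    is_contam <- obs %in% contam
    bio_samples <- sprintf("bio_%02d", seq_len(n_bio))
    ctrl_samples <- sprintf("ctrl_%02d", seq_len(n_ctrl))
    smp <- c(bio_samples, ctrl_samples)
    ref_conc <- 10  # reference biological concentration (arbitrary units)
    conc <- c(stats::rlnorm(n_bio, log(ref_conc), 0.6),
              stats::rlnorm(n_ctrl, log(0.5), 0.6))
    names(conc) <- smp
    # biological community: log-normal base abundances
    base <- stats::rlnorm(n_obs, 0, 1)
    base[is_contam] <- 0
    # per-contaminant level, in expected relative frequency at the reference
    # concentration: expected reads per biological sample ~ depth_mean * level,
    # kept near 1-3 so contaminants are only partially prevalent in
    # biological samples while dominating the low-biomass controls
    level <- stats::rlnorm(n_obs, log(8e-5), 0.7)
    level[!is_contam] <- 0
    counts <- matrix(0L, n_obs, length(smp), dimnames = list(obs, smp))
    unassigned <- integer(length(smp))
    for (s in seq_along(smp)) {
      is_ctrl <- s > n_bio
      bio_part <- if (is_ctrl) {
        # carry-over: rare, heavily diluted biological signal
        base * stats::rbinom(n_obs, 1, 0.1) * 0.01 *
          stats::rlnorm(n_obs, 0, 0.5)
      } else {
        base * stats::rlnorm(n_obs, 0, 0.5)
      }
      bio_part <- if (sum(bio_part) > 0) bio_part / sum(bio_part) *
        (if (is_ctrl) 0.01 else 1) else bio_part
      contam_part <- level / conc[s] * ref_conc *
        stats::rlnorm(n_obs, 0, noise_sd) * is_contam
      p <- bio_part + contam_part
      if (sum(p) == 0) p <- rep(1 / n_obs, n_obs)
      depth <- stats::rpois(1, depth_mean * conc[s] / ref_conc) + 1L
      counts[, s] <- stats::rmultinom(1, depth, p / sum(p))[, 1L]
      unassigned[s] <- stats::rpois(1, 0.03 * depth)
    }
    table <- count_table(counts, unassigned = unassigned)
    md <- metadata(
      data.frame(sample_type = ifelse(smp %in% ctrl_samples, "control",
                                      "biological"),
                 dna_conc = unname(conc),
                 batch = sample(paste0("batch", 1:4), length(smp),
                                replace = TRUE),
                 row.names = smp, stringsAsFactors = FALSE),
      kinds = c(sample_type = "categorical", dna_conc = "numeric",
                batch = "categorical"))
    controls <- control_groups(list(negative_controls = ctrl_samples), table)
    tax <- toy_taxonomy(obs, seed_genera = sample.int(1e6, 1))
    structure(list(table = table, metadata = md, controls = controls,
                   taxonomy = tax, truth = contam,
                   params = list(n_bio = n_bio, n_ctrl = n_ctrl,
                                 n_obs = n_obs, n_contam = n_contam,
                                 seed = seed, noise_sd = noise_sd,
                                 depth_mean = depth_mean)),
              class = "synthetic_study")
  })
}

# two-rank toy taxonomy: root > genus > species; species ids are the
# observation ids, genus assignment is seeded
toy_taxonomy <- function(obs, seed_genera = 1) {
  n_gen <- max(2L, ceiling(length(obs) / 4))
  genera <- sprintf("g%02d", seq_len(n_gen))
  assign_g <- with_seed(seed_genera,
                        sample(genera, length(obs), replace = TRUE))
  nodes <- rbind(
    data.frame(id = "root", parent = "root", rank = "no rank", name = "root",
               stringsAsFactors = FALSE),
    data.frame(id = genera, parent = "root", rank = "genus",
               name = paste0("Genus_", genera), stringsAsFactors = FALSE),
    data.frame(id = obs, parent = assign_g, rank = "species",
               name = paste0("Species_", obs), stringsAsFactors = FALSE))
  taxonomy_db(nodes, ranks = c("genus", "species"))
}

#' @export
print.synthetic_study <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "synthetic_study: %d obs x (%d biological + %d control) samples, %d planted contaminants (seed %d)\n",
    p$n_obs, p$n_bio, p$n_ctrl, p$n_contam, p$seed))
  invisible(x)
}

#' Write a synthetic study to the on-disk formats the CLI consumes
#'
#' Emits `counts.tsv`, `metadata.tsv`, `controls_negative.txt`,
#' `taxonomy.tsv` (generic-tsv dialect) and `truth.txt` into `dir`.
#'
#' @param study a `synthetic_study`
#' @param dir output directory (created if needed)
#' @return named character vector of the written paths
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             controls = file.path(dir, "controls_negative.txt"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             truth = file.path(dir, "truth.txt"))
  write_count_table(study$table, paths[["counts"]], "tsv")
  md <- data.frame(sample = rownames(study$metadata),
                   as.data.frame(study$metadata), check.names = FALSE)
  utils::write.table(md, paths[["metadata"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c("# negative control samples",
               study$controls$negative_controls), paths[["controls"]])
  tax <- study$taxonomy
  nodes <- data.frame(id = names(tax$parent), parent = unname(tax$parent),
                      rank = unname(tax$rank[names(tax$parent)]),
                      name = unname(tax$name[names(tax$parent)]))
  utils::write.table(nodes, paths[["taxonomy"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(study$truth, paths[["truth"]])
  paths
}
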