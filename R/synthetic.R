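#' Specification for a synthetic compound benchmark set
#'
#' Describes a clustered chemical library with the statistical structure the
#' calibration exploits: compounds in a cluster share a scaffold (hence high
#' pairwise Tanimoto similarity) and share a systematic docking-score bias,
#' emulating the system-dependent error of real scoring functions. True
#' binding free energies are drawn per compound; the observed docking score is
#' `score_slope * true_dg + score_intercept + cluster_bias + noise` with the
#' bias drawn once per cluster and the noise per compound.
#'
#' @param n_clusters Number of chemical series (>= 2), default 5.
#' @param compounds_per_cluster Compounds per series (>= 3), default 20.
#' @param dg_range_kcal Range the true binding energies are drawn from
#'   (uniform), default \[-12, -5\] kcal/mol.
#' @param score_slope,score_intercept Linear map from true energy to the
#'   ideal (bias-free) docking score; defaults 1 and 0.
#' @param cluster_bias_sd SD of the per-cluster score bias (kcal/mol),
#'   default 1.5.
#' @param noise_sd SD of the per-compound score noise (kcal/mol), default 0.5.
#' @param seed RNG seed.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_clusters = 5L, compounds_per_cluster = 20L,
                           dg_range_kcal = c(-12, -5), score_slope = 1,
                           score_intercept = 0, cluster_bias_sd = 1.5,
                           noise_sd = 0.5, seed = 1L) {
  if (n_clusters < 2L) abort("n_clusters must be >= 2", class = "dockcal_config_error")
  if (compounds_per_cluster < 3L) {
    abort("compounds_per_cluster must be >= 3", class = "dockcal_config_error")
  }
  if (cluster_bias_sd < 0 || noise_sd < 0) {
    abort("standard deviations must be non-negative", class = "dockcal_config_error")
  }
  if (length(dg_range_kcal) != 2L || any(dg_range_kcal >= 0) ||
      dg_range_kcal[1] > dg_range_kcal[2]) {
    abort("dg_range_kcal must be an increasing pair of negative energies",
          class = "dockcal_config_error")
  }
  structure(
    list(n_clusters = as.integer(n_clusters),
         compounds_per_cluster = as.integer(compounds_per_cluster),
         dg_range_kcal = dg_range_kcal, score_slope = score_slope,
         score_intercept = score_intercept, cluster_bias_sd = cluster_bias_sd,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# ring-system scaffolds, each with one substitution slot
SCAFFOLDS <- c(
  "c1ccc(%s)cc1",              # benzene
  "c1ccc(%s)nc1",              # pyridine
  "c1ccc2ccc(%s)cc2c1",        # naphthalene
  "c1ccc2[nH]c(%s)cc2c1",      # indole
  "c1ccc2nc(%s)ccc2c1",        # quinoline
  "c1cc(%s)co1",               # furan
  "c1cc(%s)cs1",               # thiophene
  "c1cnc(%s)nc1",              # pyrimidine
  "c1c[nH]c(%s)n1",            # imidazole
  "C1CCC(%s)CC1",              # cyclohexane
  "C1CCN(%s)CC1",              # piperidine
  "c1cc2ccccc2o1"              # benzofuran (parent; substituted via suffix)
)

# small substituent groups written as SMILES prefixes for the slot
SUBSTITUENTS <- c("C", "CC", "CCC", "C(C)C", "O", "OC", "N", "NC",
                  "F", "Cl", "Br", "C(=O)O", "C(=O)N", "C#N")

# groups whose trailing atom can take one more bond, usable as the first
# half of a two-group chain (halogens and nitriles are terminal)
LINKER_SUBSTITUENTS <- setdiff(SUBSTITUENTS, c("F", "Cl", "Br", "C#N"))

#' Generate a synthetic clustered compound set
#'
#' Draws scaffolds (one per cluster, without replacement from a built-in list
#' of ring systems) and enumerates substituted analogues within each cluster,
#' so that within-cluster fingerprint similarity is chemically real rather
#' than simulated. Energies, biases and noise are drawn as described in
#' [synthetic_spec()]. Deterministic given the seed; the caller's RNG state
#' is left untouched.
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble with columns `id`, `cluster_id`, `smiles`, `true_dg`
#'   (kcal/mol), `docking_score` (kcal/mol) and `ki_nM` (the inverse
#'   free-energy conversion of `true_dg`).
#' @examples
#' compounds <- generate_compounds(synthetic_spec(n_clusters = 2,
#'                                                compounds_per_cluster = 3))
#' compounds$smiles
#' @export
generate_compounds <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    scaff <- sample(SCAFFOLDS, spec$n_clusters,
                    replace = spec$n_clusters > length(SCAFFOLDS))
    # substituent combinations: singles then ordered pairs, fixed order
    singles <- SUBSTITUENTS
    pairs <- as.vector(outer(LINKER_SUBSTITUENTS, SUBSTITUENTS,
                             function(a, b) paste0(a, b)))
    combos <- unique(c(singles, pairs))
    purrr::map_dfr(seq_len(spec$n_clusters), function(k) {
      picks <- sample(combos, spec$compounds_per_cluster)
      smiles <- vapply(picks, function(s) make_analog(scaff[k], s), character(1),
                       USE.NAMES = FALSE)
      true_dg <- runif(spec$compounds_per_cluster, spec$dg_range_kcal[1],
                       spec$dg_range_kcal[2])
      bias <- rnorm(1, 0, spec$cluster_bias_sd)
      noise <- rnorm(spec$compounds_per_cluster, 0, spec$noise_sd)
      tibble::tibble(
        id = sprintf("c%02d_m%03d", k, seq_len(spec$compounds_per_cluster)),
        cluster_id = k,
        smiles = smiles,
        true_dg = true_dg,
        docking_score = spec$score_slope * true_dg + spec$score_intercept +
          bias + noise,
        ki_nM = delta_g_to_ki(true_dg)
      )
    })
  })
}

make_analog <- function(template, substituent) {
  if (grepl("%s", template, fixed = TRUE)) sprintf(template, substituent)
  else paste0(substituent, template)
}

#' Write a synthetic compound set to disk in the formats the package reads
#'
#' Emits `compounds.smi` (SMILES + id), `scores.csv` (`id,docking_score`),
#' `affinities.csv` (`id,ki_nM`) and a `manifest.json` tying them together
#' with the generator settings, so the files can be fed straight back into
#' [read_molecules()], [read_affinities()] and the command-line interface.
#'
#' @param compounds Output of [generate_compounds()].
#' @param dir Output directory (created if needed).
#' @param spec Optional [synthetic_spec()] echoed into the manifest.
#' @return Path of the manifest, invisibly.
#' @export
write_dataset <- function(compounds, dir, spec = NULL) {
  stopifnot(is.data.frame(compounds),
            all(c("id", "smiles", "docking_score", "ki_nM") %in% names(compounds)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  smi <- file.path(dir, "compounds.smi")
  writeLines(paste(compounds$smiles, compounds$id), smi)
  scores <- file.path(dir, "scores.csv")
  write.csv(compounds[, c("id", "docking_score")], scores, row.names = FALSE,
            quote = FALSE)
  aff <- file.path(dir, "affinities.csv")
  write.csv(compounds[, c("id", "ki_nM")], aff, row.names = FALSE,
            quote = FALSE)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(structures = basename(smi), scores = basename(scores),
         affinities = basename(aff),
         generator = if (!is.null(spec)) unclass(spec) else NULL),
    manifest, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
  invisible(manifest)
}
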