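# Synthetic congeneric-series generator: ChEMBL-like activity
# datasets, receptor-subtype pairs with tunable scaffold overlap,
# screening libraries and toy docking scores. SMILES are built by text
# substitution at a single marked attachment point on vetted template
# scaffolds, which guarantees parseable molecules without a chemistry
# engine; activity comes from a latent model in which the scaffold
# carries the dominant effect and each substituent a smaller additive
# one (both are linear functions of the fingerprint bits those
# fragments light up), plus Gaussian assay noise.

# Two chemically distinct template families so that subtype pairs at
# scaffold overlap 0 have depressed cross-set Tanimoto similarity:
# aromatic/heteroaromatic cores vs saturated/aliphatic cores. "{R}"
# marks the attachment point.
scaffold_cores <- function(family = c("aromatic", "aliphatic")) {
  family <- match.arg(family)
  if (family == "aromatic") {
    c("c1ccc({R})cc1",            # benzene
      "c1ccc2cc({R})ccc2c1",      # naphthalen-2-yl
      "c1ccnc({R})c1",            # pyridin-2-yl
      "c1ccc({R})nc1",            # pyridin-3-yl
      "c1cc({R})ccn1",            # pyridin-4-yl
      "c1cnc({R})cn1",            # pyrimidinyl
      "c1ccc({R})o1",             # furanyl
      "c1ccc({R})s1",             # thiophenyl
      "c1ccc({R})[nH]1",          # pyrrolyl
      "c1cnc({R})[nH]1",          # imidazolyl
      "c1cc({R})on1",             # isoxazolyl
      "c1cc({R})no1",             # oxazole-regioisomer
      "COc1cccc({R})c1",          # 3-methoxyphenyl
      "Cc1ccc({R})cc1",           # 4-methylphenyl
      "Fc1ccc({R})cc1",           # 4-fluorophenyl
      "Clc1cccc({R})c1",          # 3-chlorophenyl
      "Nc1ccc({R})cc1",           # 4-aminophenyl
      "Oc1cccc({R})c1",           # 3-hydroxyphenyl
      "c1ccc(-c2ccc({R})cc2)cc1", # biphenylyl
      "c1ccc2nc({R})ccc2c1",      # quinolin-2-yl
      "c1ccc2oc({R})cc2c1",       # benzofuran-2-yl
      "c1ccc2sc({R})cc2c1",       # benzothiophen-2-yl
      "c1ccc2[nH]c({R})cc2c1",    # indol-2-yl
      "N#Cc1ccc({R})cc1")         # 4-cyanophenyl
  } else {
    c("C1CCC({R})CC1",            # cyclohexyl
      "C1CCC({R})C1",             # cyclopentyl
      "C1CC({R})C1",              # cyclobutyl
      "C1C({R})C1",               # cyclopropyl
      "C1CCN({R})CC1",            # piperidin-1-yl
      "C1CCC({R})NC1",            # piperidin-3-yl
      "C1CCOC({R})C1",            # tetrahydropyranyl
      "C1COC({R})CN1",            # morpholin-2-yl
      "C1CN({R})CCO1",            # morpholin-4-yl
      "C1CCSC({R})C1",            # thianyl
      "C1CCN({R})C1",             # pyrrolidin-1-yl
      "C1CCC({R})CN1",            # piperidin-2-yl
      "OC1CCC({R})CC1",           # 4-hydroxycyclohexyl
      "NC1CCC({R})CC1",           # 4-aminocyclohexyl
      "CC1CCC({R})CC1",           # 4-methylcyclohexyl
      "FC1CCC({R})CC1",           # 4-fluorocyclohexyl
      "C1CCC2(CC1)CCC({R})C2",    # spirodecanyl
      "C1CCC(C2CCC({R})C2)CC1",   # cyclohexyl-cyclopentyl
      "OCC({R})CO",               # 1,3-diol backbone
      "CCOC({R})CC",              # diethyl ether backbone
      "CC(C)({R})C(C)C",          # branched quaternary
      "O=C1CCC({R})CC1",          # cyclohexanonyl
      "O=C1OC({R})CC1",           # butyrolactonyl
      "C1CC2CCC1C({R})C2")        # norbornanyl
  }
}

# Scaffold templates of one family: a curated list of distinct ring
# systems or backbones with one marked attachment point. Distinct
# cores (rather than a core-times-linker grid) keep molecules from
# different scaffolds structurally distinct for the substituent pool.
scaffold_templates <- function(family) scaffold_cores(family)

# Vetted substituent fragments; all valid as a branch continuation at
# the attachment point. Extended deterministically with methylene
# prefixes when more are requested than the base pool holds.
substituent_pool <- function(n) {
  base <- c("C", "CC", "CCC", "CCCC", "C(C)C", "C(C)(C)C",
            "CO", "CCO", "CCCO", "OC", "OCC", "CN", "CCN", "NC",
            "C#N", "CC#N", "C(=O)O", "C(=O)OC", "C(=O)N", "C(=O)NC",
            "C(=O)C", "C(F)(F)F", "CCF", "COC", "CCOC", "CN(C)C",
            "CCNC", "C=C", "CC=C", "C#C", "CC#C", "CSC", "CCS",
            "S(=O)(=O)C", "CC(O)C", "OCC(O)C", "Cc1ccccc1",
            "CCc1ccccc1", "CC(N)C(=O)O", "CC(C)O")
  out <- base
  k <- 1L
  while (length(out) < n) {
    out <- unique(c(out, paste0(strrep("C", k), base)))
    k <- k + 1L
  }
  out[seq_len(n)]
}

#' Specification for the synthetic dataset generator
#'
#' Defaults produce a 2000-compound receptor library (20 scaffolds of
#' 100 substituted analogues) with a quarter of the scaffolds inactive
#' (pChEMBL 0) and 0.4 pChEMBL units of Gaussian assay noise —
#' dataset size, inactive load and noise chosen to resemble curated
#' ChEMBL receptor sets of the kind the classifier is aimed at.
#'
#' @param n_scaffolds number of scaffold templates per dataset.
#' @param substituents_per_scaffold analogues generated per scaffold.
#' @param overlap fraction of scaffolds shared between the two members
#'   of a subtype pair, in `[0, 1]`.
#' @param inactive_fraction fraction of scaffolds whose compounds are
#'   inactive (pChEMBL exactly 0).
#' @param noise_sd standard deviation of the additive pChEMBL noise.
#' @param seed integer seed; everything the generator emits is a pure
#'   function of the spec including this seed.
#' @return a `generator_spec` object.
#' @export
generator_spec <- function(n_scaffolds = 20L, substituents_per_scaffold = 100L,
                           overlap = 0, inactive_fraction = 0.25,
                           noise_sd = 0.4, seed = 1L) {
  stopifnot(n_scaffolds >= 1, substituents_per_scaffold >= 1,
            overlap >= 0, overlap <= 1,
            inactive_fraction >= 0, inactive_fraction <= 1, noise_sd >= 0)
  structure(list(n_scaffolds = as.integer(n_scaffolds),
                 substituents_per_scaffold = as.integer(substituents_per_scaffold),
                 overlap = overlap, inactive_fraction = inactive_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "generator_spec")
}

# Assemble one dataset from chosen templates and latent parameters.
# base_effect: per-scaffold latent pChEMBL; NA marks inactive
# scaffolds (all their compounds get the sentinel 0). Records are
# guaranteed structurally distinct: different (scaffold, substituent)
# texts can spell the same molecule, so candidates are canonicalized
# and colliding rows deterministically resampled from each scaffold's
# remaining substituent permutation — a congeneric library must not
# contain the same structure twice under different labels.
build_library <- function(templates, base_effect, spec, receptor, rng_seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)
  nsub <- spec$substituents_per_scaffold
  pool <- substituent_pool(max(nsub * 3L, 120L))
  sub_delta <- stats::rnorm(length(pool), 0, 0.5)
  n_scaf <- length(templates)
  # per-scaffold permutation of the pool: the first nsub are used,
  # later entries serve as replacements on structural collision
  perms <- lapply(seq_len(n_scaf), function(s) sample(length(pool)))
  next_cand <- rep(nsub + 1L, n_scaf)
  choice <- do.call(rbind, lapply(seq_len(n_scaf), function(s) {
    data.frame(scaffold = s, slot = seq_len(nsub),
               sub_idx = perms[[s]][seq_len(nsub)])
  }))
  noise <- stats::rnorm(nrow(choice), 0, spec$noise_sd)
  mk_smiles <- function(rows) {
    vapply(seq_len(nrow(rows)), function(i) {
      sub("{R}", pool[rows$sub_idx[i]], templates[rows$scaffold[i]],
          fixed = TRUE)
    }, character(1))
  }
  smiles <- mk_smiles(choice)
  canon <- canonical_smiles(smiles)
  for (round in 1:25) {
    bad <- which(duplicated(canon) | is.na(canon))
    if (!length(bad)) break
    for (i in bad) {
      s <- choice$scaffold[i]
      if (next_cand[s] > length(pool)) {
        stop("Substituent pool exhausted while de-duplicating scaffold ", s,
             call. = FALSE)
      }
      choice$sub_idx[i] <- perms[[s]][next_cand[s]]
      next_cand[s] <- next_cand[s] + 1L
    }
    smiles[bad] <- mk_smiles(choice[bad, , drop = FALSE])
    canon[bad] <- canonical_smiles(smiles[bad])
  }
  if (anyDuplicated(canon) || anyNA(canon)) {
    stop("Could not build a collision-free library", call. = FALSE)
  }
  base <- base_effect[choice$scaffold]
  p <- ifelse(is.na(base), 0,
              pmin(pmax(base + sub_delta[choice$sub_idx] + noise, 0.1), 11))
  rec <- data.frame(
    compound_id = sprintf("%s-S%02d-%03d", receptor, choice$scaffold,
                          choice$slot),
    smiles = smiles, pchembl = p,
    activity_class = assign_activity_class(p), stringsAsFactors = FALSE)
  activity_dataset(rec, receptor = receptor,
                   provenance = sprintf("synthetic (seed %d)", rng_seed))
}

# Draw per-scaffold latent parameters: which scaffolds are inactive
# and the base pChEMBL of the active ones (spread across the activity
# scale so several classes are populated).
draw_scaffold_bases <- function(n, inactive_fraction) {
  n_inact <- round(inactive_fraction * n)
  base <- stats::runif(n, 3.5, 10.2)
  if (n_inact > 0) base[sample(n, n_inact)] <- NA
  base
}

#' Generate a synthetic receptor activity library
#'
#' @param spec a [generator_spec()].
#' @param receptor receptor label stamped on the dataset.
#' @param family scaffold template family, `"aromatic"` (default) or
#'   `"aliphatic"`.
#' @return an `activity_dataset` of
#'   `n_scaffolds * substituents_per_scaffold` labeled records; every
#'   SMILES is parseable by construction.
#' @export
generate_receptor_library <- function(spec, receptor = "SYN1",
                                      family = "aromatic") {
  stopifnot(inherits(spec, "generator_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  grid <- scaffold_templates(family)
  if (spec$n_scaffolds > length(grid)) {
    stop("At most ", length(grid), " scaffolds per family", call. = FALSE)
  }
  templates <- sample(grid, spec$n_scaffolds)
  bases <- draw_scaffold_bases(spec$n_scaffolds, spec$inactive_fraction)
  build_library(templates, bases, spec, receptor, rng_seed = spec$seed + 1L)
}

#' Generate a receptor-subtype dataset pair with controlled scaffold
#' overlap
#'
#' The two datasets share `round(overlap * n_scaffolds)` scaffold
#' templates; the remainder are drawn from chemically distinct
#' families (aromatic for A, aliphatic for B), so cross-set Tanimoto
#' similarity rises monotonically with the overlap. Shared scaffolds
#' keep the same latent base activity in both datasets (the chemotype
#' is what transfers between paralogous receptors), while substituent
#' effects and noise are drawn independently per dataset, so shared
#' scaffolds still differ in per-compound activity — the selectivity
#' signal.
#'
#' @param spec a [generator_spec()]; `spec$overlap` controls sharing.
#' @param receptors character vector of two labels.
#' @return list with `activity_dataset` elements `A` and `B`.
#' @export
generate_subtype_pair <- function(spec, receptors = c("SYNA", "SYNB")) {
  stopifnot(inherits(spec, "generator_spec"), length(receptors) == 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_scaffolds
  n_shared <- round(spec$overlap * n)
  gridA <- scaffold_templates("aromatic")
  gridB <- scaffold_templates("aliphatic")
  if (n > length(gridA) || n > length(gridB)) {
    stop("At most ", min(length(gridA), length(gridB)),
         " scaffolds per family", call. = FALSE)
  }
  pickA <- sample(gridA, n)
  shared <- pickA[seq_len(n_shared)]
  ownA <- if (n_shared > 0) pickA[-seq_len(n_shared)] else pickA
  ownB <- sample(gridB, n - n_shared)
  shared_base <- draw_scaffold_bases(n_shared, spec$inactive_fraction)
  ownA_base <- draw_scaffold_bases(n - n_shared, spec$inactive_fraction)
  ownB_base <- draw_scaffold_bases(n - n_shared, spec$inactive_fraction)
  A <- build_library(c(shared, ownA), c(shared_base, ownA_base), spec,
                     receptors[1], rng_seed = spec$seed + 101L)
  B <- build_library(c(shared, ownB), c(shared_base, ownB_base), spec,
                     receptors[2], rng_seed = spec$seed + 202L)
  list(A = A, B = B)
}

#' Generate toy docking scores
#'
#' Gaussian binding affinities (kcal/mol, more negative = stronger),
#' a fixed number of poses per compound.
#'
#' @param ids compound identifiers.
#' @param seed integer seed.
#' @param mean,sd affinity distribution parameters (kcal/mol).
#' @param n_poses poses per compound (default 10).
#' @return a `dock_scores` data.frame: `compound_id`, `pose_index`,
#'   `affinity`, `source`.
#' @export
generate_dock_scores <- function(ids, seed = 1L, mean = -8, sd = 1.5,
                                 n_poses = 10L) {
  if (length(ids) == 0) stop("ids must be non-empty", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  df <- data.frame(
    compound_id = rep(as.character(ids), each = n_poses),
    pose_index = rep(seq_len(n_poses), times = length(ids)),
    affinity = stats::rnorm(length(ids) * n_poses, mean, sd),
    source = "synthetic", stringsAsFactors = FALSE)
  class(df) <- c("dock_scores", class(df))
  df
}
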