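#' Synthetic lipidome simulation
#'
#' Generates lipidome tables with the statistical structure the analysis
#' pipeline assumes -- a two-factor (genotype x temperature) randomized
#' complete block design replicated over experimental runs, multiplicative
#' lognormal measurement noise, class composition shares, heat-effect
#' multipliers by lipid category, genotype-specific remodeling strength,
#' recurrent QC-pool samples, and planted quality-control violations --
#' together with the ground truth needed for parameter-recovery checks.
#'
#' @name synthetic-data
NULL

# Default species roster: 192 analytes across 22 headgroup classes, built
# from the acyl chains observed in peanut leaf lipidomes (16:0..24:1, with
# oxidized ;O forms on 18:2/18:3/18:4). Weights are within-class relative
# abundances (normalized at generation time).
.roster_entry <- function(class, species, weights) {
  stopifnot(length(species) == length(weights))
  tibble::tibble(name = species, class = class, weight = weights)
}

.default_roster <- function() {
  di <- function(cls, chains, w) {
    .roster_entry(cls, paste(cls, chains), w)
  }
  rbind(
    di("DGDG",
       c("18:3_18:3", "18:3_16:0", "18:3_18:2", "18:3_16:1", "18:2_16:0",
         "18:2_18:2", "18:3_18:1", "18:2_18:1", "18:1_16:0", "16:0_16:0",
         "18:0_16:0", "18:0_18:3", "18:3_20:1", "18:3_20:2", "18:3_20:3",
         "18:1_18:1", "18:0_18:2", "16:0_16:1",
         # oxidized species (12)
         "16:0_18:3;O", "18:3_18:3;O", "18:2_18:3;O", "16:0_18:2;O",
         "18:3_18:2;O", "16:0_18:4;O", "18:3_18:4;O", "18:2_18:4;O",
         "16:0_18:1;O", "18:1_18:3;O", "18:0_18:3;O", "16:1_18:3;O"),
       c(0.62, 0.12, 0.05, 0.04, 0.03, 0.025, 0.02, 0.015, 0.012, 0.01,
         0.01, 0.008, 0.007, 0.006, 0.005, 0.005, 0.004, 0.004,
         rep(0.002, 12))),
    di("MGDG",
       c("18:3_18:3", "18:3_16:0", "18:3_16:1", "18:2_18:3", "18:3_18:1",
         "18:2_16:0", "18:2_18:2", "16:0_16:0", "18:1_16:0", "18:0_16:0",
         "17:0_18:3", "20:1_18:3", "20:2_18:3", "20:3_18:3", "18:0_18:3",
         # oxidized species (5)
         "18:4;O_16:0", "18:4;O_18:3", "18:3;O_18:3", "18:2;O_16:0",
         "18:3;O_16:0"),
       c(0.72, 0.08, 0.05, 0.035, 0.02, 0.02, 0.015, 0.01, 0.008, 0.007,
         0.006, 0.006, 0.005, 0.004, 0.004, rep(0.002, 5))),
    di("SQDG",
       c("18:3_16:0", "18:3_18:3", "18:2_16:0", "16:0_16:0", "18:1_16:0",
         "18:0_16:0", "18:4;O_16:0"),
       c(0.5, 0.25, 0.1, 0.08, 0.04, 0.03, 0.005)),
    di("PG",
       c("18:3_16:1", "18:3_16:0", "18:2_16:1", "18:2_16:0", "16:0_16:1",
         "16:0_16:0", "18:1_16:0", "18:3_18:3", "18:0_16:0", "18:1_16:1"),
       c(0.3, 0.25, 0.12, 0.1, 0.08, 0.06, 0.04, 0.02, 0.02, 0.02)),
    di("PA",
       c("18:3_16:0", "18:3_18:3", "18:2_16:0", "18:2_18:2", "16:0_18:1",
         "16:0_16:0", "18:0_18:2"),
       c(0.35, 0.2, 0.18, 0.1, 0.08, 0.05, 0.04)),
    di("PC",
       c("16:0_18:3", "16:0_18:2", "18:2_18:2", "18:2_18:3", "18:3_18:3",
         "16:0_18:1", "18:1_18:2", "18:1_18:3", "18:0_18:2", "16:0_16:0",
         "18:0_18:3", "16:1_18:2", "20:0_18:2", "20:1_18:2", "22:0_18:2",
         "22:1_18:2", "22:2_18:2",
         "16:0_18:3;O", "18:2_18:3;O", "16:0_18:2;O", "18:3_18:3;O"),
       c(0.22, 0.2, 0.13, 0.12, 0.08, 0.07, 0.06, 0.04, 0.03, 0.02,
         0.02, 0.015, 0.01, 0.008, 0.007, 0.005, 0.005, rep(0.003, 4))),
    di("PE",
       c("16:0_18:2", "16:0_18:3", "18:2_18:2", "18:2_18:3", "18:1_18:2",
         "16:0_18:1", "18:3_18:3", "18:0_18:2", "16:1_18:2", "20:0_18:2",
         "20:2_18:3", "20:3_18:3", "24:0_18:2", "24:1_18:2",
         "16:0_18:3;O", "18:2_18:3;O", "16:0_18:2;O"),
       c(0.25, 0.2, 0.13, 0.1, 0.07, 0.06, 0.05, 0.04, 0.03, 0.02,
         0.015, 0.015, 0.01, 0.01, rep(0.003, 3))),
    .roster_entry("PE-N", c("PE-N 34:2", "PE-N 36:4", "PE-N 36:5"),
                  c(0.5, 0.3, 0.2)),
    di("PI",
       c("16:0_18:2", "16:0_18:3", "18:2_18:2", "18:2_18:3", "16:0_18:1",
         "18:0_18:2", "16:1_18:2", "18:3_18:3", "18:1_18:2"),
       c(0.3, 0.25, 0.12, 0.1, 0.08, 0.06, 0.04, 0.03, 0.02)),
    di("PS",
       c("16:0_18:2", "16:0_18:3", "18:0_18:2", "22:0_18:2", "16:1_18:2",
         "24:0_18:2"),
       c(0.3, 0.22, 0.18, 0.12, 0.1, 0.08)),
    di("LPC", c("16:0", "18:2", "18:3", "18:1"), c(0.35, 0.3, 0.2, 0.15)),
    di("LPE", c("16:0", "18:2", "18:3"), c(0.4, 0.35, 0.25)),
    di("MGMG", c("18:3", "16:0"), c(0.7, 0.3)),
    di("DGMG", c("18:3", "16:0"), c(0.7, 0.3)),
    di("TrGDG", c("18:3_18:3", "18:3_16:0"), c(0.7, 0.3)),
    di("acMGDG", c("18:3_18:3_18:3", "16:0_18:3_18:3", "18:3_18:3_18:2"),
       c(0.5, 0.3, 0.2)),
    di("DG",
       c("18:3_18:3", "16:0_18:3", "16:0_18:2", "18:2_18:2", "16:0_18:1",
         "18:1_18:2"),
       c(0.3, 0.25, 0.2, 0.1, 0.08, 0.07)),
    di("TG",
       c("18:3_18:3_18:3", "18:3_18:3_18:2", "18:2_18:3_18:2",
         "16:0_18:3_18:3", "16:0_18:3_18:2", "18:2_18:2_18:2",
         "16:0_18:2_18:2", "16:0_16:0_18:2", "16:0_18:1_18:2",
         "18:1_18:2_18:2", "18:1_18:3_18:2", "18:1_18:1_18:2",
         "16:0_16:0_18:3", "16:0_18:1_18:3", "18:0_18:2_18:2",
         "18:0_18:3_18:2", "16:0_16:0_16:0", "16:0_16:0_18:1",
         "18:1_18:1_18:1", "18:0_18:1_18:2", "18:0_18:0_18:2",
         "16:0_18:0_18:2", "18:1_18:1_18:3", "18:0_18:3_18:3"),
       c(0.14, 0.12, 0.1, 0.09, 0.08, 0.06, 0.06, 0.04, 0.04, 0.035,
         0.035, 0.03, 0.03, 0.025, 0.02, 0.02, 0.015, 0.015, 0.015,
         0.012, 0.01, 0.01, 0.01, 0.008)),
    .roster_entry("SE", c("sitosterol 18:2", "sitosterol 18:3"),
                  c(0.45, 0.55)),
    .roster_entry("SG",
                  c("Sitosterol-Glc", "Stigmasterol-Glc", "Campesterol-Glc"),
                  c(0.6, 0.25, 0.15)),
    .roster_entry("ASG",
                  c("Sitosterol-Glc 16:0", "Sitosterol-Glc 18:2",
                    "Sitosterol-Glc 18:3", "Stigmasterol-Glc 16:0",
                    "Stigmasterol-Glc 18:2", "Stigmasterol-Glc 18:3",
                    "Campesterol-Glc 16:0", "Campesterol-Glc 18:2",
                    "Campesterol-Glc 18:3"),
                  c(0.2, 0.18, 0.17, 0.1, 0.09, 0.08, 0.07, 0.06, 0.05)),
    .roster_entry("GSL", c("GSL 34:1;O2", "GSL 42:2;O3"), c(0.6, 0.4))
  )
}

# Default class composition shares (fraction of total signal). The six major
# classes take stated shares; the remainder is spread over the minor classes
# and normalized to fill the rest exactly.
.default_shares <- function() {
  major <- c(MGDG = 0.49, DGDG = 0.29, PC = 0.075, PE = 0.04, PG = 0.035,
             PI = 0.02)
  minor <- c(SQDG = 0.012, PA = 0.005, PS = 0.003, DG = 0.005, TG = 0.008,
             SE = 0.0015, SG = 0.002, ASG = 0.003, `PE-N` = 0.002,
             LPC = 0.002, LPE = 0.0015, MGMG = 0.001, DGMG = 0.001,
             TrGDG = 0.001, acMGDG = 0.0015, GSL = 0.0015)
  minor <- minor * (1 - sum(major)) / sum(minor)
  c(major, minor)
}

#' Simulation configuration
#'
#' Bundles the study-design dimensions, composition shares, species roster,
#' heat-effect multiplier ranges by lipid category, genotype tolerance
#' distribution, noise levels and planted QC violations.
#'
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   same configuration and seed.
#' @param n_genotypes Number of genotypes (default 54).
#' @param n_runs Experimental runs (default 2).
#' @param n_blocks Blocks (replications) per run (default 3).
#' @param n_qc_pool Recurrent QC-pool samples (default 8).
#' @param base_total Grand total signal per mg in a typical sample
#'   (default 2.0 internal-standard-normalized units).
#' @param shares Named vector of class composition shares summing to 1;
#'   default: MGDG 0.49, DGDG 0.29, PC 0.075, PE 0.04, PG 0.035, PI 0.02,
#'   remainder spread over the minor classes.
#' @param roster Species roster tibble (`name`, `class`, `weight`); default
#'   a representative 192-species roster.
#' @param mult_membrane_183,mult_tg_183,mult_se,mult_sg,mult_ox,mult_asg,mult_other
#'   Length-2 ranges of the uniform distributions the per-analyte HT
#'   multipliers are drawn from, by category: 18:3-containing membrane
#'   diacyl species U(0.53, 0.75); 18:3-containing TG U(1.9, 2.2);
#'   SE U(2.5, 5.4); SG U(1.05, 1.4); oxidized species U(0.4, 0.8);
#'   ASG U(0.4, 0.9); everything else U(0.9, 1.1).
#' @param g_range Range of the per-genotype tolerance parameter g in
#'   \[0, 1\]; the effective HT multiplier of genotype i is `M^g_i`, so g
#'   ranks genotypes by remodeling strength. Default U(0.5, 1).
#' @param g_override Optional explicit vector of length `n_genotypes` of
#'   tolerance parameters in \[0, 1\], e.g. to program known strong
#'   remodelers; overrides `g_range` sampling.
#' @param sdlog_resid Residual lognormal sd on the log scale (default 0.15).
#' @param sdlog_geno,sdlog_run,sdlog_block Lognormal sd of genotype
#'   baseline, run and block effects (defaults 0.05).
#' @param qc_cv Coefficient of variation of QC-pool measurements
#'   (default 0.1).
#' @param n_planted_cv,n_planted_lod Planted QC violations: analytes given
#'   a QC CV above 0.3 (default 3) and analytes scaled below the limit of
#'   detection (default 2).
#' @param planted_cv_value CV given to the planted CV violators
#'   (default 0.45).
#' @param planted_lod_mean Mean amount given to the planted LOD violators
#'   (default 2e-5).
#' @return A list of class `remodel_config`.
#' @export
remodel_config <- function(seed = 1L,
                           n_genotypes = 54L, n_runs = 2L, n_blocks = 3L,
                           n_qc_pool = 8L,
                           base_total = 2.0,
                           shares = .default_shares(),
                           roster = .default_roster(),
                           mult_membrane_183 = c(0.53, 0.75),
                           mult_tg_183 = c(1.9, 2.2),
                           mult_se = c(2.5, 5.4),
                           mult_sg = c(1.05, 1.4),
                           mult_ox = c(0.4, 0.8),
                           mult_asg = c(0.4, 0.9),
                           mult_other = c(0.9, 1.1),
                           g_range = c(0.5, 1),
                           g_override = NULL,
                           sdlog_resid = 0.15,
                           sdlog_geno = 0.05,
                           sdlog_run = 0.05,
                           sdlog_block = 0.05,
                           qc_cv = 0.1,
                           n_planted_cv = 3L, n_planted_lod = 2L,
                           planted_cv_value = 0.45,
                           planted_lod_mean = 2e-5) {
  roster <- tibble::as_tibble(roster)
  if (anyDuplicated(roster$name)) stop("duplicate species in roster")
  if (abs(sum(shares) - 1) > 1e-8) stop("class shares must sum to 1")
  missing <- setdiff(unique(roster$class), names(shares))
  if (length(missing) > 0) {
    stop("roster classes without a share: ", paste(missing, collapse = ", "))
  }
  ranges <- list(mult_membrane_183, mult_tg_183, mult_se, mult_sg, mult_ox,
                 mult_asg, mult_other)
  if (any(vapply(ranges, function(r) any(r <= 0), logical(1)))) {
    stop("multiplier ranges must be positive")
  }
  if (g_range[1] < 0 || g_range[2] > 1 || g_range[1] > g_range[2]) {
    stop("g_range must lie within [0, 1]")
  }
  if (!is.null(g_override)) {
    if (length(g_override) != n_genotypes ||
        any(g_override < 0 | g_override > 1)) {
      stop("g_override must give one value in [0, 1] per genotype")
    }
  }
  structure(
    list(seed = as.integer(seed), n_genotypes = as.integer(n_genotypes),
         n_runs = as.integer(n_runs), n_blocks = as.integer(n_blocks),
         n_qc_pool = as.integer(n_qc_pool), base_total = base_total,
         shares = shares, roster = roster,
         mult_membrane_183 = mult_membrane_183, mult_tg_183 = mult_tg_183,
         mult_se = mult_se, mult_sg = mult_sg, mult_ox = mult_ox,
         mult_asg = mult_asg, mult_other = mult_other,
         g_range = g_range, g_override = g_override,
         sdlog_resid = sdlog_resid,
         sdlog_geno = sdlog_geno, sdlog_run = sdlog_run,
         sdlog_block = sdlog_block, qc_cv = qc_cv,
         n_planted_cv = as.integer(n_planted_cv),
         n_planted_lod = as.integer(n_planted_lod),
         planted_cv_value = planted_cv_value,
         planted_lod_mean = planted_lod_mean),
    class = "remodel_config"
  )
}

# category of an analyte for multiplier assignment
.analyte_category <- function(species) {
  cls <- species$headgroup$name
  if (species$total_extra_oxygens > 0L) return("ox")
  if (cls == "SE") return("se")
  if (cls == "SG") return("sg")
  if (cls == "ASG") return("asg")
  has_183 <- species$acyl_resolved &&
    contains_chain(species, "18:3")
  if (cls == "TG" && has_183) return("tg_183")
  if (isTRUE(species$headgroup$is_membrane_diacyl) && has_183) {
    return("membrane_183")
  }
  "other"
}

#' Generate a synthetic lipidome table with ground truth
#'
#' Amounts follow a multiplicative model: class share x within-class species
#' weight x genotype baseline x block and run effects x (HT multiplier
#' `M^g_i` when treated) x lognormal noise. QC-pool samples are drawn around
#' the grand mean composition with the configured CV; planted QC violations
#' are injected last.
#'
#' @param config A [remodel_config()].
#' @return A list with `table` (a [lipidome_table()]) and `truth`, a list
#'   with `analytes` (tibble: `analyte`, `class`, `category`, `multiplier`,
#'   `expected_fold` = mean over genotypes of `multiplier^g_i` -- the
#'   population-level fold the pipeline estimates), `genotypes` (tibble:
#'   `genotype`, `g`), and `qc_violations` (tibble: `analyte`, `type`).
#' @export
generate_lipidome <- function(config = remodel_config()) {
  stopifnot(inherits(config, "remodel_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  roster <- config$roster
  species <- lapply(roster$name, parse_species)
  names(species) <- roster$name
  p <- nrow(roster)

  # expected amount per analyte in a baseline sample
  w_norm <- stats::ave(roster$weight, roster$class,
                       FUN = function(w) w / sum(w))
  base_mean <- config$base_total * config$shares[roster$class] * w_norm

  # per-analyte HT multiplier by category
  category <- vapply(species, .analyte_category, character(1))
  range_of <- list(ox = config$mult_ox, se = config$mult_se,
                   sg = config$mult_sg, asg = config$mult_asg,
                   tg_183 = config$mult_tg_183,
                   membrane_183 = config$mult_membrane_183,
                   other = config$mult_other)
  multiplier <- vapply(seq_len(p), function(i) {
    r <- range_of[[category[i]]]
    stats::runif(1, r[1], r[2])
  }, numeric(1))

  genotypes <- sprintf("G%02d", seq_len(config$n_genotypes))
  g <- if (!is.null(config$g_override)) {
    as.numeric(config$g_override)
  } else {
    stats::runif(config$n_genotypes, config$g_range[1], config$g_range[2])
  }
  geno_eff <- stats::rnorm(config$n_genotypes, 0, config$sdlog_geno)
  run_eff <- stats::rnorm(config$n_runs, 0, config$sdlog_run)
  block_eff <- matrix(stats::rnorm(config$n_runs * config$n_blocks, 0,
                                   config$sdlog_block),
                      config$n_runs, config$n_blocks)

  design <- expand.grid(genotype = seq_len(config$n_genotypes),
                        treatment = c("OT", "HT"),
                        run = seq_len(config$n_runs),
                        block = seq_len(config$n_blocks),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_exp <- nrow(design)

  log_base <- matrix(log(base_mean), n_exp, p, byrow = TRUE)
  log_geno <- geno_eff[design$genotype]
  log_blk <- run_eff[design$run] + block_eff[cbind(design$run, design$block)]
  is_ht <- design$treatment == "HT"
  # HT effect: log(M_a) * g_i for treated samples
  log_ht <- outer(ifelse(is_ht, 1, 0) * g[design$genotype], log(multiplier))
  noise <- matrix(stats::rnorm(n_exp * p, 0, config$sdlog_resid), n_exp, p)
  amounts <- exp(log_base + log_geno + log_blk + log_ht + noise)

  sample_id <- sprintf("R%dB%d_%s_%s", design$run, design$block,
                       genotypes[design$genotype], design$treatment)
  rownames(amounts) <- sample_id

  # QC pool: drawn around the grand mean composition with the configured CV
  grand_mean <- colMeans(amounts)
  sdq <- sqrt(log(1 + config$qc_cv^2))
  qc <- matrix(
    grand_mean[rep(seq_len(p), each = config$n_qc_pool)] *
      exp(stats::rnorm(config$n_qc_pool * p, -sdq^2 / 2, sdq)),
    config$n_qc_pool, p
  )
  qc_ids <- sprintf("QC%02d", seq_len(config$n_qc_pool))
  rownames(qc) <- qc_ids

  # planted QC violations: fixed zero-mean pattern gives the CV violators an
  # exact sample CV; LOD violators are rescaled below the detection limit
  # plant only in unremarkable minor-class analytes so that composition
  # shares and programmed fold changes stay undisturbed
  minor_class <- config$shares[roster$class] <= 0.01
  eligible <- which(category == "other" & minor_class)
  planted_cv <- roster$name[eligible[seq_len(config$n_planted_cv)]]
  remaining <- setdiff(eligible, eligible[seq_len(config$n_planted_cv)])
  planted_lod <- roster$name[remaining[seq_len(config$n_planted_lod)]]
  for (a in planted_cv) {
    j <- match(a, roster$name)
    pat <- rep_len(c(-1, 1), config$n_qc_pool)
    pat <- pat - mean(pat)
    pat <- pat / stats::sd(pat)
    qc[, j] <- grand_mean[j] * (1 + config$planted_cv_value * pat)
  }
  for (a in planted_lod) {
    j <- match(a, roster$name)
    scale_to <- config$planted_lod_mean / mean(amounts[, j])
    amounts[, j] <- amounts[, j] * scale_to
    qc[, j] <- qc[, j] * scale_to
  }

  all_amounts <- rbind(amounts, qc)
  colnames(all_amounts) <- roster$name
  samples <- tibble::tibble(
    sample_id = c(sample_id, qc_ids),
    genotype = c(genotypes[design$genotype], rep(NA_character_,
                                                 config$n_qc_pool)),
    treatment = c(design$treatment, rep(NA_character_, config$n_qc_pool)),
    run = c(design$run, rep(NA_integer_, config$n_qc_pool)),
    block = c(design$block, rep(NA_integer_, config$n_qc_pool)),
    is_qc_pool = c(rep(FALSE, n_exp), rep(TRUE, config$n_qc_pool))
  )
  table <- lipidome_table(samples, all_amounts)

  truth <- list(
    analytes = tibble::tibble(
      analyte = roster$name, class = roster$class, category = category,
      multiplier = multiplier,
      expected_fold = vapply(multiplier, function(m) mean(m^g), numeric(1))
    ),
    genotypes = tibble::tibble(genotype = genotypes, g = g),
    qc_violations = tibble::tibble(
      analyte = c(planted_cv, planted_lod),
      type = c(rep("CV", length(planted_cv)), rep("LOD", length(planted_lod)))
    ),
    config = config
  )
  list(table = table, truth = truth)
}

#' Generate a synthetic marker set
#'
#' Markers are allocated to chromosomes multinomially with probabilities
#' proportional to chromosome size times a per-chromosome enrichment factor,
#' then placed uniformly within the chromosome.
#'
#' @param layout A [genome_layout()].
#' @param n Number of markers (>= 0).
#' @param enrichment Per-chromosome enrichment factors (> 0); either a
#'   single value, a vector matching `layout$chrom`, or a named vector of
#'   factors for a subset (others default to 1).
#' @param seed Integer seed.
#' @return A [marker_set()] with attribute `"enrichment"` holding the
#'   factors used.
#' @export
generate_markers <- function(layout, n, enrichment = 1, seed = 1L) {
  if (n < 0) stop("n must be >= 0")
  k <- nrow(layout)
  if (!is.null(names(enrichment))) {
    f <- rep(1, k)
    idx <- match(names(enrichment), layout$chrom)
    if (anyNA(idx)) stop("enrichment names must be chromosome names")
    f[idx] <- enrichment
  } else {
    f <- rep_len(enrichment, k)
  }
  if (any(f <= 0)) stop("enrichment factors must be > 0")
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  prob <- layout$size_mb * f
  counts <- if (n > 0) {
    as.integer(stats::rmultinom(1, n, prob = prob))
  } else rep(0L, k)
  chrom <- rep(layout$chrom, counts)
  pos <- unlist(lapply(seq_len(k), function(i) {
    if (counts[i] == 0) return(numeric(0))
    ceiling(stats::runif(counts[i], 0, layout$size_mb[i] * 1e6))
  }))
  if (length(pos) == 0) pos <- numeric(0)
  out <- marker_set(chrom, pos, layout = layout)
  attr(out, "enrichment") <- stats::setNames(f, layout$chrom)
  out
}
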