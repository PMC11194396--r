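# Ground-truth simulator for cis-eQTL / disease-GWAS summary statistics.
#
# Summary statistics are simulated directly in z-score space from the
# multivariate normal implied by the region's LD structure -- no
# individual-level genotypes are generated. For a region of m variants with
# genotype correlation matrix S (AR(1): S_ij = ld_rho^|i-j|) and sparse
# causal standardized effects b, the marginal standardized effects are
# lambda = S b, the expected z-scores are sqrt(n_eff) * lambda, and the
# observed z-scores add correlated noise ~ MVN(0, S). Binary outcomes live
# on the log-odds scale with effective sample size n * cf * (1 - cf).

#' Simulation configuration
#'
#' Defines the generative conditions of a synthetic study. Defaults emulate
#' the scale of a blood cis-eQTL meta-analysis (exposure, n ~ 31,684) and a
#' large type-2-diabetes case-control meta-analysis (outcome, 62,892 cases /
#' 596,424 controls) with a moderate causal effect of expression on disease
#' liability.
#'
#' @param n_genes Number of gene regions.
#' @param variants_per_region Variants per cis region.
#' @param ld_rho AR(1) genotype correlation parameter in \[0, 1).
#' @param n_exp Exposure (eQTL) sample size; per-variant sizes vary
#'   uniformly within 95-100% of it, as in real eQTL meta-analyses.
#' @param n_out Outcome study sample size.
#' @param outcome_type `"binary"` (disease, log-odds scale) or
#'   `"quantitative"`.
#' @param case_fraction Case fraction of a binary outcome.
#' @param theta True causal effect of expression on the outcome (log-OR per
#'   SD of expression for binary outcomes). Length 1 or `n_genes`.
#' @param scenario One of `"causal"`, `"null"`, `"reverse"`,
#'   `"shared_variant"`, `"distinct_variant"`, `"pleiotropic"`. Length 1 or
#'   `n_genes`.
#' @param maf_range Range of minor-allele frequencies.
#' @param eqtl_effect_size Standardized effect of each causal eQTL variant
#'   on expression (SD of expression per SD of genotype).
#' @param n_causal_exp Number of causal eQTL variants per gene, spread
#'   across the region so they survive LD clumping as independent
#'   instruments.
#' @param gwas_effect_size Standardized effect of the outcome's own causal
#'   variant in `"reverse"` and `"distinct_variant"` scenarios.
#' @param theta_rev True effect of the outcome on expression in the
#'   `"reverse"` scenario.
#' @param pleiotropy_effect Direct (horizontal) standardized effect on the
#'   outcome at causal-variant positions in the `"pleiotropic"` scenario.
#' @param target_z Expected causal-variant z-score used by the
#'   `"shared_variant"` and `"distinct_variant"` colocalization scenarios.
#' @param distinct_gap Positions separating the two causal variants in the
#'   `"distinct_variant"` scenario.
#' @param scramble_alleles If `TRUE` (default), outcome rows are emitted
#'   with randomly swapped or strand-complemented allele orientation so
#'   harmonization is exercised end to end.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 1,
                       variants_per_region = 50,
                       ld_rho = 0.5,
                       n_exp = 31684,
                       n_out = 659316,
                       outcome_type = c("binary", "quantitative"),
                       case_fraction = 62892 / 659316,
                       theta = 0.4,
                       scenario = "causal",
                       maf_range = c(0.05, 0.5),
                       eqtl_effect_size = 0.07,
                       n_causal_exp = 2,
                       gwas_effect_size = 0.25,
                       theta_rev = 0.2,
                       pleiotropy_effect = 0.01,
                       target_z = 8,
                       distinct_gap = 20,
                       scramble_alleles = TRUE,
                       seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  scenarios <- c("causal", "null", "reverse", "shared_variant",
                 "distinct_variant", "pleiotropic")
  if (!all(scenario %in% scenarios)) {
    abort_config(paste0("unknown scenario: ",
                        paste(setdiff(scenario, scenarios), collapse = ", ")))
  }
  if (ld_rho < 0 || ld_rho >= 1) abort_config("ld_rho must lie in [0, 1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5) {
    abort_config("maf_range must be within (0, 0.5]")
  }
  cfg <- list(
    n_genes = n_genes, variants_per_region = variants_per_region,
    ld_rho = ld_rho, n_exp = n_exp, n_out = n_out,
    outcome_type = outcome_type, case_fraction = case_fraction,
    theta = rep_len(theta, n_genes), scenario = rep_len(scenario, n_genes),
    maf_range = maf_range, eqtl_effect_size = eqtl_effect_size,
    n_causal_exp = n_causal_exp, gwas_effect_size = gwas_effect_size,
    theta_rev = theta_rev, pleiotropy_effect = pleiotropy_effect,
    target_z = target_z, distinct_gap = distinct_gap,
    scramble_alleles = scramble_alleles, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# stream ids: one RNG stream per (gene, purpose) so per-gene output is
# reproducible independently of iteration order
stream_seed <- function(config, gene_index, stream) {
  derive_seed(config$seed, gene_index * 1000 + stream)
}

ar1_chol <- function(m, rho) {
  s <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
  chol(s)
}

# Deterministic region skeleton: positions, frequencies, alleles, causal
# architecture and the standardized marginal effect vectors for both traits.
region_structure <- function(config, gene_index) {
  m <- config$variants_per_region
  # recycle so replicate-style calls (gene_index > n_genes) are valid
  idx <- ((gene_index - 1) %% length(config$scenario)) + 1
  scenario <- config$scenario[idx]
  theta <- config$theta[((gene_index - 1) %% length(config$theta)) + 1]
  with_seed(stream_seed(config, gene_index, 0), {
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    eaf <- ifelse(stats::runif(m) < 0.5, maf, 1 - maf)
    alleles <- t(vapply(seq_len(m), function(i) sample(VALID_ALLELES, 2),
                        character(2)))
    n_exp_i <- round(config$n_exp * stats::runif(m, 0.95, 1))

    # genes cycle over 22 autosomes so positions stay within integer range
    chrom <- as.character((gene_index - 1) %% 22 + 1)
    region_start <- 5e5 + ((gene_index - 1) %/% 22) * 5e6
    pos <- as.integer(region_start + (seq_len(m) - 1) * 4000L)
    tss <- as.integer(region_start + (m %/% 2) * 4000L)

    s <- config$ld_rho^abs(outer(seq_len(m), seq_len(m), "-"))

    # causal architecture per scenario
    b_exp <- numeric(m)
    b_out_direct <- numeric(m)   # outcome's own standardized effects
    causal_exp <- integer(0)
    causal_out <- integer(0)
    neff_out <- effective_n_out(config)

    if (scenario %in% c("causal", "null", "pleiotropic")) {
      causal_exp <- unique(round(seq(1, m, length.out = config$n_causal_exp + 2)))
      causal_exp <- causal_exp[-c(1, length(causal_exp))]
      b_exp[causal_exp] <- config$eqtl_effect_size
      if (scenario != "null") causal_out <- causal_exp
      if (scenario == "pleiotropic") {
        b_out_direct[causal_exp] <- config$pleiotropy_effect
      }
    } else if (scenario == "reverse") {
      causal_out <- max(1L, m %/% 2L)
      b_out_direct[causal_out] <- config$gwas_effect_size
    } else if (scenario == "shared_variant") {
      causal_exp <- max(1L, m %/% 2L)
      causal_out <- causal_exp
      b_exp[causal_exp] <- config$target_z / sqrt(config$n_exp)
      b_out_direct[causal_out] <- config$target_z / sqrt(neff_out)
    } else if (scenario == "distinct_variant") {
      causal_exp <- max(1L, (m - config$distinct_gap) %/% 2L)
      causal_out <- causal_exp + config$distinct_gap
      if (causal_out > m) abort_config("distinct_gap exceeds region size")
      b_exp[causal_exp] <- config$target_z / sqrt(config$n_exp)
      b_out_direct[causal_out] <- config$target_z / sqrt(neff_out)
    }

    lambda_exp <- as.vector(s %*% b_exp)
    eta_out <- switch(scenario,
      causal = theta * lambda_exp,
      pleiotropic = theta * lambda_exp + as.vector(s %*% b_out_direct),
      null = numeric(m),
      reverse = as.vector(s %*% b_out_direct),
      shared_variant = as.vector(s %*% b_out_direct),
      distinct_variant = as.vector(s %*% b_out_direct)
    )
    if (scenario == "reverse") {
      # expression is downstream of disease: its marginal signal is the
      # disease signal attenuated by the reverse effect
      lambda_exp <- config$theta_rev * eta_out
      causal_exp <- integer(0)
    }

    gene_id <- sprintf("ENSG%08d", gene_index)
    list(
      gene = tibble::tibble(
        gene_id = gene_id, symbol = paste0("GENE", gene_index),
        chrom = chrom, tss = tss, cis_window_bp = 1e6
      ),
      variant_id = sprintf("rs%d_%03d", gene_index, seq_len(m)),
      chrom = rep(chrom, m), pos = pos, maf = maf, eaf = eaf,
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      n_exp_i = n_exp_i, sigma = s, chol_u = chol(s),
      lambda_exp = lambda_exp, eta_out = eta_out,
      truth = list(
        gene_id = gene_id, scenario = scenario,
        theta = if (scenario == "null") 0 else theta,
        theta_rev = if (scenario == "reverse") config$theta_rev else 0,
        causal_exp = as.integer(causal_exp),
        causal_out = as.integer(causal_out),
        pleiotropy = if (scenario == "pleiotropic") config$pleiotropy_effect else 0
      )
    )
  })
}

effective_n_out <- function(config) {
  if (config$outcome_type == "binary") {
    config$n_out * config$case_fraction * (1 - config$case_fraction)
  } else {
    config$n_out
  }
}

# Draw one study's associations for a region: z = sqrt(neff) * mu + L' eps
draw_associations <- function(st, mu, neff, n_report, seed,
                              scramble = FALSE) {
  m <- length(st$variant_id)
  with_seed(seed, {
    z <- sqrt(neff) * mu + as.vector(crossprod(st$chol_u, stats::rnorm(m)))
    se <- 1 / sqrt(2 * st$maf * (1 - st$maf) * neff)
    tbl <- tibble::tibble(
      variant_id = st$variant_id,
      chrom = st$chrom,
      pos = st$pos,
      effect_allele = st$effect_allele,
      other_allele = st$other_allele,
      eaf = st$eaf,
      beta = z * se,
      se = se,
      pval = pmax(two_sided_p(z), 1e-320),
      n = rep_len(n_report, m)
    )
    if (scramble) {
      u <- stats::runif(m)
      swap <- u < 1 / 3
      comp <- u >= 1 / 3 & u < 2 / 3
      tbl$beta[swap] <- -tbl$beta[swap]
      tbl$eaf[swap] <- 1 - tbl$eaf[swap]
      ea <- tbl$effect_allele
      tbl$effect_allele[swap] <- tbl$other_allele[swap]
      tbl$other_allele[swap] <- ea[swap]
      tbl$effect_allele[comp] <- complement_allele(tbl$effect_allele[comp])
      tbl$other_allele[comp] <- complement_allele(tbl$other_allele[comp])
    }
    tbl
  })
}

#' Simulate one gene region
#'
#' Generates exposure (eQTL) and outcome (GWAS) summary statistics, the LD
#' r-squared matrix, and the ground-truth record for a single gene region
#' under the configured scenario. With the same `config` and `gene_index`
#' the output is byte-identical; `outcome_rep > 1` redraws only the outcome
#' noise (the region structure and exposure stay fixed), which is how
#' independent validation outcomes over the same truth are produced.
#'
#' @param config A [sim_config()] object.
#' @param gene_index Gene index in `1:n_genes`.
#' @param outcome_rep Outcome noise replicate (1 = discovery outcome).
#' @return A list with `gene` (region tibble row), `exposure`, `outcome`
#'   (sumstats tibbles), `ld` (r-squared matrix), and `truth`.
#' @export
simulate_region <- function(config, gene_index, outcome_rep = 1) {
  st <- region_structure(config, gene_index)
  m <- length(st$variant_id)
  exposure <- draw_associations(
    st, st$lambda_exp, neff = st$n_exp_i, n_report = st$n_exp_i,
    seed = stream_seed(config, gene_index, 1)
  )
  exposure$gene_id <- st$gene$gene_id
  neff <- effective_n_out(config)
  outcome <- draw_associations(
    st, st$eta_out, neff = neff, n_report = config$n_out,
    seed = stream_seed(config, gene_index, 10 + outcome_rep),
    scramble = config$scramble_alleles
  )
  ld <- st$sigma^2
  dimnames(ld) <- list(st$variant_id, st$variant_id)
  list(gene = st$gene, exposure = exposure, outcome = outcome, ld = ld,
       truth = st$truth)
}

#' Simulate a complete multi-gene study bundle
#'
#' Assembles everything the pipeline consumes: an exposure eQTL table over
#' all genes, a discovery outcome, optional re-noised validation outcomes
#' over the same ground truth, optional quantitative biomarker outcomes,
#' per-gene LD matrices, the gene-region table, the druggable-gene list and
#' the ground-truth records.
#'
#' @param config A [sim_config()] object.
#' @param n_validation Number of validation outcome replicates.
#' @param biomarker_spec Optional tibble with columns `outcome_id`,
#'   `gene_id` (`NA` for a biomarker unaffected by any gene), `effect`
#'   (standardized effect of expression on the biomarker) and optionally
#'   `n` (GWAS size, default 100,000).
#' @return A `study_bundle` list with elements `exposure`, `outcome`,
#'   `validation` (named list), `biomarkers` (named list), `genes`, `ld`
#'   (named list), `gene_list`, `truth`, `config`.
#' @export
simulate_study <- function(config, n_validation = 0, biomarker_spec = NULL) {
  genes <- list(); expo <- list(); outc <- list(); lds <- list(); truth <- list()
  valid <- lapply(seq_len(n_validation), function(r) list())
  structures <- list()
  for (g in seq_len(config$n_genes)) {
    reg <- simulate_region(config, g)
    genes[[g]] <- reg$gene
    expo[[g]] <- reg$exposure
    outc[[g]] <- reg$outcome
    lds[[reg$gene$gene_id]] <- reg$ld
    truth[[reg$gene$gene_id]] <- reg$truth
    structures[[g]] <- region_structure(config, g)
    for (r in seq_len(n_validation)) {
      valid[[r]][[g]] <- simulate_region(config, g, outcome_rep = 1 + r)$outcome
    }
  }
  genes <- dplyr::bind_rows(genes)

  bin <- config$outcome_type == "binary"
  n_cases <- if (bin) round(config$n_out * config$case_fraction) else NULL
  n_controls <- if (bin) config$n_out - n_cases else NULL
  mk_outcome <- function(slices, id) {
    as_sumstats(dplyr::bind_rows(slices), trait_id = id,
                trait_type = if (bin) "binary" else "quantitative",
                n_cases = n_cases, n_controls = n_controls)
  }
  exposure <- as_sumstats(dplyr::bind_rows(expo), trait_id = "expression",
                          trait_type = "quantitative")
  outcome <- mk_outcome(outc, "disease_discovery")
  validation <- stats::setNames(
    lapply(seq_len(n_validation), function(r) {
      mk_outcome(valid[[r]], paste0("disease_validation_", r))
    }),
    if (n_validation > 0) paste0("disease_validation_", seq_len(n_validation))
  )

  biomarkers <- list()
  if (!is.null(biomarker_spec)) {
    biomarker_spec <- tibble::as_tibble(biomarker_spec)
    if (!"n" %in% names(biomarker_spec)) biomarker_spec$n <- 1e5
    for (b in seq_len(nrow(biomarker_spec))) {
      spec <- biomarker_spec[b, ]
      slices <- lapply(seq_len(config$n_genes), function(g) {
        st <- structures[[g]]
        mu <- if (!is.na(spec$gene_id) && st$gene$gene_id == spec$gene_id) {
          spec$effect * st$lambda_exp
        } else {
          numeric(length(st$variant_id))
        }
        draw_associations(st, mu, neff = spec$n, n_report = spec$n,
                          seed = stream_seed(config, g, 100 + b),
                          scramble = config$scramble_alleles)
      })
      biomarkers[[spec$outcome_id]] <- as_sumstats(
        dplyr::bind_rows(slices), trait_id = spec$outcome_id,
        trait_type = "quantitative"
      )
    }
  }

  structure(
    list(exposure = exposure, outcome = outcome, validation = validation,
         biomarkers = biomarkers, genes = genes, ld = lds,
         gene_list = genes$gene_id, truth = truth, config = config),
    class = "study_bundle"
  )
}

#' Write a simulated study bundle to disk
#'
#' Emits exactly the plain-text inputs the pipeline consumes: exposure and
#' outcome TSVs, per-gene LD TSVs, the gene-region TSV, the one-id-per-line
#' druggable-gene list, and the ground truth as JSON.
#'
#' @param bundle A bundle from [simulate_study()], or a [sim_config()] (in
#'   which case the bundle is simulated first).
#' @param dir Output directory (created if needed).
#' @param ... Passed to [simulate_study()] when `bundle` is a config.
#' @return The directory path, invisibly.
#' @export
generate_study <- function(bundle, dir, ...) {
  if (inherits(bundle, "sim_config")) bundle <- simulate_study(bundle, ...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "ld"), showWarnings = FALSE)
  write_sumstats(bundle$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(bundle$outcome, file.path(dir, "outcome_discovery.tsv"))
  for (nm in names(bundle$validation)) {
    write_sumstats(bundle$validation[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }
  for (nm in names(bundle$biomarkers)) {
    write_sumstats(bundle$biomarkers[[nm]],
                   file.path(dir, paste0("biomarker_", nm, ".tsv")))
  }
  utils::write.table(bundle$genes, file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(bundle$gene_list, file.path(dir, "druggable_genes.txt"))
  for (nm in names(bundle$ld)) {
    write_ld_matrix(bundle$ld[[nm]], file.path(dir, "ld", paste0(nm, ".tsv")))
  }
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a study bundle back from disk
#'
#' @param dir Directory written by [generate_study()].
#' @param outcome_type,n_cases,n_controls Trait metadata for the disease
#'   outcomes (not recoverable from the TSVs themselves).
#' @return A `study_bundle` list (without a `config` element).
#' @export
load_study <- function(dir, outcome_type = "binary", n_cases = NULL,
                       n_controls = NULL) {
  genes <- read_gene_regions(file.path(dir, "genes.tsv"))
  exposure <- read_sumstats(file.path(dir, "exposure.tsv"),
                            trait_id = "expression")
  outcome <- read_sumstats(file.path(dir, "outcome_discovery.tsv"),
                           trait_id = "disease_discovery",
                           trait_type = outcome_type,
                           n_cases = n_cases, n_controls = n_controls)
  val_files <- list.files(dir, pattern = "^disease_validation_.*\\.tsv$")
  validation <- stats::setNames(lapply(val_files, function(f) {
    read_sumstats(file.path(dir, f),
                  trait_id = sub("\\.tsv$", "", f),
                  trait_type = outcome_type,
                  n_cases = n_cases, n_controls = n_controls)
  }), sub("\\.tsv$", "", val_files))
  bio_files <- list.files(dir, pattern = "^biomarker_.*\\.tsv$")
  biomarkers <- stats::setNames(lapply(bio_files, function(f) {
    read_sumstats(file.path(dir, f),
                  trait_id = sub("^biomarker_(.*)\\.tsv$", "\\1", f))
  }), sub("^biomarker_(.*)\\.tsv$", "\\1", bio_files))
  lds <- stats::setNames(
    lapply(genes$gene_id, function(g) {
      read_ld_matrix(file.path(dir, "ld", paste0(g, ".tsv")))
    }),
    genes$gene_id
  )
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(
    list(exposure = exposure, outcome = outcome, validation = validation,
         biomarkers = biomarkers, genes = genes, ld = lds,
         gene_list = read_gene_list(file.path(dir, "druggable_genes.txt")),
         truth = truth, config = NULL),
    class = "study_bundle"
  )
}
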