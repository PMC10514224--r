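#' Run the full pipeline: simulate, (optionally) quantify, analyze
#'
#' Executes simulate-cohort -> (simulate-pet -> quantify, when
#' `simulate_pet = TRUE`) -> preprocess -> the three analysis steps, and
#' writes tidy CSV outputs plus a run manifest with a checksum for every
#' output file.  When `simulate_pet = FALSE` (the default, mirroring
#' that binding can come from a precomputed table) the binding
#' observations are generated directly on the log scale.
#'
#' @param gen_config a [generator_config()]
#' @param config a [run_config()]; `config$seed` drives every stage
#' @param outdir output directory (created if needed)
#' @param simulate_pet if `TRUE`, raw plasma/TAC files are simulated and
#'   quantified for every PET subject (slower; exercises the kinetic
#'   stage end to end)
#' @return the run manifest (list), invisibly written as
#'   `manifest.csv`
#' @export
run_all <- function(gen_config = generator_config(),
                    config = run_config(), outdir = "petbpf-run",
                    simulate_pet = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  cohort <- stage("simulate-cohort", {
    ch <- generate_cohort(gen_config, config$seed)
    write_cohort(ch, file.path(outdir, "cohort.csv"))
    ch
  })

  binding <- if (simulate_pet) {
    stage("simulate-pet+quantify", {
      truth_b <- generate_binding(cohort, gen_config, config$seed)
      pet_ids <- unique(truth_b$subject_id)
      obs <- lapply(seq_along(pet_ids), function(i) {
        sid <- pet_ids[i]
        target <- exp(truth_b$log_bpf[truth_b$subject_id == sid])
        names(target) <- truth_b$region[truth_b$subject_id == sid]
        subj <- generate_pet_subject(target, gen_config,
                                     seed = config$seed + 10L * i)
        plasma_path <- file.path(outdir, sprintf("plasma_%s.tsv", sid))
        tac_path <- file.path(outdir, sprintf("tacs_%s.tsv", sid))
        write_plasma(subj$plasma, plasma_path)
        write_tacs(subj$tacs, tac_path)
        quant <- quantify_subject(read_plasma(plasma_path),
                                  read_tacs(tac_path), config)
        make_binding_observations(quant, sid)
      })
      do.call(rbind, obs)
    })
  } else {
    stage("simulate-binding", generate_binding(cohort, gen_config, config$seed))
  }
  utils::write.csv(binding, file.path(outdir, "binding.csv"),
                   row.names = FALSE)

  merged <- stage("preprocess", {
    m <- prepare_binding(binding, cohort)
    utils::write.csv(attr(m, "censoring"),
                     file.path(outdir, "censoring_audit.csv"),
                     row.names = FALSE)
    m
  })

  res <- stage("analyze", {
    # a degenerate preliminary model (e.g. logistic separation on a tiny
    # simulated cohort) is recorded rather than aborting the run
    prelim <- tryCatch(preliminary_models(cohort, config),
                       error = function(e) conditionMessage(e))
    s1 <- lapply(meth_sites(), function(site) {
      step1_methylation(cohort, "stress", site, config)
    })
    names(s1) <- meth_sites()
    s2 <- step2_bpf_exposure(merged, "stress", config)
    s3 <- step3_bpf_methylation(merged, config)
    list(prelim = prelim, s1 = s1, s2 = s2, s3 = s3)
  })

  step1_tab <- do.call(rbind, lapply(meth_sites(), function(site) {
    tab <- res$s1[[site]]$coef
    tab$site <- paste0("-", site)
    tab
  }))
  utils::write.csv(step1_tab, file.path(outdir, "step1_methylation.csv"),
                   row.names = FALSE)
  utils::write.csv(res$s2$mixed$coef,
                   file.path(outdir, "step2_mixed_coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(res$s2$regionwise,
                   file.path(outdir, "table2_regionwise_stress.csv"),
                   row.names = FALSE)
  utils::write.csv(res$s3$mixed$coef,
                   file.path(outdir, "step3_mixed_coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(res$s3$regionwise,
                   file.path(outdir, "table3_regionwise_methylation.csv"),
                   row.names = FALSE)

  files <- list.files(outdir, pattern = "\\.csv$|\\.tsv$", full.names = TRUE)
  files <- setdiff(files, file.path(outdir, "manifest.csv"))
  manifest <- list(
    config_hash = substr(tools::md5sum(
      textConnection2write(c(deparse(gen_config), deparse(unclass(config))),
                           outdir)), 1, 32),
    seed = config$seed,
    outputs = data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files))),
    timings = timings,
    package_version = as.character(utils::packageVersion("petbpf"))
  )
  utils::write.csv(
    data.frame(key = c("config_hash", "seed", "package_version"),
               value = c(manifest$config_hash, manifest$seed,
                         manifest$package_version)),
    file.path(outdir, "manifest.csv"), row.names = FALSE
  )
  utils::write.csv(manifest$outputs, file.path(outdir, "checksums.csv"),
                   row.names = FALSE)
  manifest
}

# hash helper: md5 of a text blob via a temp file (tools::md5sum wants a path)
textConnection2write <- function(lines, outdir) {
  p <- file.path(tempdir(), "petbpf-config-hash.txt")
  writeLines(lines, p)
  p
}
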