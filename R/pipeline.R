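# End-to-end orchestration: simulate (optional) -> read/dedup -> pileup ->
# damage -> consensus -> haplogroup -> contamination, with a combined JSON
# report.

#' Default pipeline configuration
#'
#' Returns the full configuration list with defaults; [run_pipeline()] merges
#' user values over it. `sam = NULL` selects simulation mode (reads are
#' generated from the endogenous/contaminant haplotypes), otherwise the given
#' alignments are analyzed as-is.
#'
#' @return named list of configuration values.
#' @export
default_run_config <- function() {
  list(
    ref_fasta = NULL, tree_tsv = NULL, endo_tsv = NULL, contam_tsv = NULL,
    sam = NULL, out_dir = NULL, node = "U1a1a", seed = 1L,
    n_fragments = 20000L, contamination = 0.02, frag_len_mean = 68,
    frag_len_sd = 15, delta5 = 0.25, delta3 = 0.25, rho = 0.6,
    udg_residual = 1, seq_error = 0.001, duplication_rate = 4,
    min_mapq = 30L, min_baseq = 20L, min_cov = 10L, min_frac = 0.7,
    filter_damage = TRUE, mixture = TRUE, ci = "wilson", mixture_eps = 0.005,
    damage_K = 25L
  )
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Values are coerced: `true`/`false` to logical, numbers to numeric,
#' anything else kept as text.
#'
#' @param path config file.
#' @return named list, suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[lines != ""]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    out[[key]] <- if (tolower(val) %in% c("true", "false")) {
      as.logical(toupper(val))
    } else if (grepl("^-?[0-9.eE+]+$", val) && !is.na(suppressWarnings(as.numeric(val)))) {
      as.numeric(val)
    } else {
      val
    }
  }
  out
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[mtauth:%s] %s", stage, paste0(...)))
}

#' Run the full authentication pipeline
#'
#' Stages execute in dependency order; every stage's outputs are written to
#' the output directory and the final JSON report aggregates fragment
#' statistics, the damage-profile summary, the consensus difference counts,
#' the haplogroup ranking, and all contamination estimates, plus MD5
#' checksums of the written files. Identical configuration and seed give
#' identical report content. On stage failure a `FAILED` marker naming the
#' stage is left in the output directory and the error is re-raised.
#'
#' @param config named list overriding [default_run_config()]; `out_dir` is
#'   required, and either `sam` (analysis-only) or simulation parameters.
#' @return the report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(default_run_config(), config)
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(cfg$out_dir, "FAILED")
  if (file.exists(marker)) unlink(marker)
  stage <- "setup"
  run <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)), marker)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  written <- character(0)
  emit <- function(path) {
    written <<- c(written, path)
    path
  }

  ref <- run("reference", {
    if (is.null(cfg$ref_fasta)) mt_example_reference() else read_reference_fasta(cfg$ref_fasta)
  })
  tree <- run("tree", {
    if (is.null(cfg$tree_tsv)) mt_example_tree() else read_haplogroup_tree(cfg$tree_tsv)
  })

  sim_truth <- NULL
  sam_path <- cfg$sam
  if (is.null(sam_path)) {
    run("simulate", {
      endo <- if (is.null(cfg$endo_tsv)) mt_example_endogenous() else read_haplotype_tsv(cfg$endo_tsv, ref)
      contam <- if (is.null(cfg$contam_tsv)) mt_example_contaminant() else read_haplotype_tsv(cfg$contam_tsv, ref)
      params <- sim_params(
        n_fragments = cfg$n_fragments, frag_len_mean = cfg$frag_len_mean,
        frag_len_sd = cfg$frag_len_sd, contamination = cfg$contamination,
        delta5 = cfg$delta5, delta3 = cfg$delta3, rho = cfg$rho,
        udg_residual = cfg$udg_residual, seq_error = cfg$seq_error,
        duplication_rate = cfg$duplication_rate, seed = cfg$seed
      )
      pipeline_log("simulate", sprintf(
        "%d fragments, contamination %.3f, seed %d",
        params$n_fragments, params$contamination, params$seed
      ))
      sim <- simulate_reads(ref, endo, contam, params)
      sam_path <- emit(file.path(cfg$out_dir, "reads.sam"))
      write_sam(sim$reads, ref, sam_path)
      sim_truth <- sim$truth
      jsonlite::write_json(
        list(
          contaminant_fraction = sim$truth$contaminant_fraction,
          mean_length = sim$truth$mean_length,
          n_emitted = nrow(sim$truth$reads)
        ),
        emit(file.path(cfg$out_dir, "sim_truth.json")),
        auto_unbox = TRUE, digits = NA
      )
    })
  }

  reads <- run("read", {
    pipeline_log("read", "loading ", sam_path)
    read_alignments(sam_path, min_mapq = cfg$min_mapq, min_baseq = cfg$min_baseq)
  })
  dd <- run("deduplicate", deduplicate(reads))
  pipeline_log("deduplicate", sprintf("duplicate fraction %.4f", dd$duplicate_fraction))

  pileup <- run("pileup", {
    p <- build_pileup(dd$reads, ref)
    write_pileup_tsv(p, emit(file.path(cfg$out_dir, "pileup.tsv")))
    p
  })
  profile <- run("damage", {
    pr <- misincorporation_profile(dd$reads, ref, K = cfg$damage_K)
    write_damage_tsv(pr, emit(file.path(cfg$out_dir, "damage_profile.tsv")))
    pr
  })
  fstats <- run("damage", fragment_length_stats(dd$reads))

  cons <- run("consensus", {
    cc <- call_consensus(pileup, ref, min_cov = cfg$min_cov, min_frac = cfg$min_frac)
    write_fasta(consensus_sequence(cc), emit(file.path(cfg$out_dir, "consensus.fa")),
                name = paste0(ref$name, "_consensus"))
    write_haplotype_tsv(cc$haplotype, emit(file.path(cfg$out_dir, "variants.tsv")))
    write_vcf(cc, ref, emit(file.path(cfg$out_dir, "variants.vcf")))
    cc
  })
  vt <- variant_table(cons)

  scores <- run("haplogroup", score_haplogroups(cons$haplotype, tree, ref))
  node <- cfg$node %||% scores$node[1]
  sites <- run("haplogroup", suppressWarnings(diagnostic_positions(tree, node, ref)))

  contam_out <- run("contamination", {
    unfiltered <- estimate_diagnostic(pileup, sites, ci = cfg$ci, boot_seed = cfg$seed)
    res <- list(unfiltered = unfiltered)
    if (isTRUE(cfg$filter_damage)) {
      filt <- damage_filter_sites(sites, pileup, profile)
      res$filtered <- estimate_diagnostic(
        pileup, filt$sites, ci = cfg$ci, boot_seed = cfg$seed,
        method_tag = "diagnostic_filtered"
      )
      res$excluded_sites <- filt$excluded
    }
    if (isTRUE(cfg$mixture)) {
      endo_vec <- genome_vector(ref, cons$haplotype)
      contam_hap <- if (is.null(cfg$contam_tsv)) mt_example_contaminant() else read_haplotype_tsv(cfg$contam_tsv, ref)
      panel <- list(genome_vector(ref, contam_hap))
      mx <- estimate_mixture(dd$reads, endo_vec, panel, eps = cfg$mixture_eps)
      mx$loglik <- NULL
      mx$grid <- NULL
      res$mixture <- mx
    }
    res
  })

  report <- run("report", {
    est_json <- function(e) {
      if (is.null(e)) return(NULL)
      list(
        method = e$method, rate = e$rate, ci_low = e$ci_low, ci_high = e$ci_high,
        ci_level = e$ci_level, n_positions = e$n_positions, n_bases = e$n_bases,
        n_nonconsensus = e$n_nonconsensus, flags = as.list(e$flags)
      )
    }
    # paths are excluded from the report so that identical analyses in
    # different directories produce byte-identical reports
    cfg_rep <- cfg[setdiff(names(cfg), c("out_dir", "sam", "ref_fasta", "tree_tsv", "endo_tsv", "contam_tsv"))]
    rep <- list(
      seed = cfg$seed,
      config = cfg_rep[order(names(cfg_rep))],
      duplicate_fraction = dd$duplicate_fraction,
      fragment_stats = list(
        n = fstats$n, mean_length = fstats$mean_length,
        median_length = fstats$median_length
      ),
      damage = list(
        K = profile$K,
        terminal_ct_rate = profile$terminal_ct_rate,
        terminal_ga_rate = profile$terminal_ga_rate
      ),
      consensus = list(
        n_variants = nrow(cons$haplotype),
        diff_count = vt$n_diff,
        diff_count_all = vt$n_total,
        n_uncalled = sum(cons$calls == "N")
      ),
      haplogroups = utils::head(
        data.frame(node = scores$node, expected = scores$expected,
                   matched = scores$matched, score = scores$score), 5L
      ),
      contamination = Filter(Negate(is.null), list(
        unfiltered = est_json(contam_out$unfiltered),
        filtered = est_json(contam_out$filtered),
        mixture = est_json(contam_out$mixture)
      )),
      truth = if (!is.null(sim_truth)) {
        list(
          contaminant_fraction = sim_truth$contaminant_fraction,
          mean_length = sim_truth$mean_length
        )
      },
      files = as.list(stats::setNames(
        tools::md5sum(sort(written)), basename(sort(written))
      ))
    )
    jsonlite::write_json(
      rep, file.path(cfg$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows", null = "null"
    )
    rep
  })
  pipeline_log("done", "report written to ", file.path(cfg$out_dir, "report.json"))
  invisible(report)
}
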