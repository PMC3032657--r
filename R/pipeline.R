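#' Pipeline configuration
#'
#' Bundles inputs and analysis parameters for [run_pipeline()]. Exactly one
#' of `input_dir` (a fixture directory as written by [write_fixtures()]) or
#' `simulate` (a [sim_config()]) must be given.
#'
#' @param input_dir directory with `genes/`, `ssr.csv`, `populations.csv`.
#' @param simulate a [sim_config()] to generate the study instead.
#' @param maf_threshold minor-allele-frequency filter for LD (default 0.05).
#' @param rarefaction_n rarefaction size (`NULL` = per-locus minimum).
#' @param bootstrap_B PIC bootstrap replicates (default 10000).
#' @param amova_perms AMOVA permutations (default 15000).
#' @param percentile LD-threshold percentile (default 95).
#' @param seed integer seed for all stochastic stages.
#' @param outdir output directory.
#' @param plots write PNG heat/decay plots (default TRUE).
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, simulate = NULL,
                            maf_threshold = 0.05, rarefaction_n = NULL,
                            bootstrap_B = 10000, amova_perms = 15000,
                            percentile = 95, seed = 1L,
                            outdir = tempfile("popgenld_run_"), plots = TRUE) {
  if (is.null(input_dir) == is.null(simulate)) {
    stopf("exactly one of input_dir or simulate must be given")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  if (!is.null(input_dir)) {
    if (!dir.exists(file.path(input_dir, "genes"))) {
      stopf("input_dir %s has no genes/ directory", input_dir)
    }
    for (f in c("ssr.csv", "populations.csv")) {
      if (!file.exists(file.path(input_dir, f))) {
        stopf("input_dir %s is missing %s", input_dir, f)
      }
    }
  }
  stopifnot(is_prob(maf_threshold), is_count(bootstrap_B),
            is_count(amova_perms), percentile > 0, percentile < 100)
  structure(list(input_dir = input_dir, simulate = simulate,
                 maf_threshold = maf_threshold, rarefaction_n = rarefaction_n,
                 bootstrap_B = as.integer(bootstrap_B),
                 amova_perms = as.integer(amova_perms),
                 percentile = percentile, seed = as.integer(seed),
                 outdir = outdir, plots = isTRUE(plots)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  fields <- config[c("input_dir", "maf_threshold", "rarefaction_n",
                     "bootstrap_B", "amova_perms", "percentile", "seed")]
  fields$simulate <- if (is.null(config$simulate)) NULL else
    unclass(config$simulate)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Assemble the per-gene summary table
#'
#' One row per gene in the shape of the survey's gene summary: fragment
#' length, gene-coverage string, lines, SNPs (non-synonymous in
#' parentheses), dN/dS, indels, haplotypes, Hd +- SD, pi (exon-restricted in
#' parentheses), Tajima's D, intra-genic mean r2; plus a totals row summing
#' length, SNPs, indels and haplotypes.
#'
#' @param gene_rows list of per-gene result lists, each with `diversity`
#'   (from [diversity_summary()]), `coverage`, `omega`, `mean_r2`.
#' @return data.frame including the totals row.
#' @export
summarize_gene_table <- function(gene_rows) {
  rows <- lapply(gene_rows, function(g) {
    d <- g$diversity
    data.frame(
      gene_id = d$gene_id, length_bp = d$length_bp, coverage = g$coverage,
      n_lines = d$n_lines, n_snps = d$S, n_snps_nonsyn = d$n_snps_nonsyn,
      dn_ds = g$omega, n_indels = d$n_indels,
      n_haplotypes = d$n_haplotypes, Hd = d$Hd, Hd_sd = d$Hd_sd,
      pi = d$pi, pi_exon = d$pi_exon, tajima_D = d$tajima_D,
      tajima_p = d$tajima_p, mean_r2 = g$mean_r2,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  total_snps <- sum(out$n_snps)
  totals <- data.frame(
    gene_id = "Total", length_bp = sum(out$length_bp), coverage = "",
    n_lines = NA_integer_, n_snps = total_snps,
    n_snps_nonsyn = sum(out$n_snps_nonsyn), dn_ds = NA_real_,
    n_indels = sum(out$n_indels), n_haplotypes = sum(out$n_haplotypes),
    Hd = NA_real_, Hd_sd = NA_real_, pi = NA_real_, pi_exon = NA_real_,
    tajima_D = NA_real_, tajima_p = NA_real_,
    mean_r2 = NA_real_, stringsAsFactors = FALSE)
  out <- rbind(out, totals)
  attr(out, "bp_per_snp") <- if (total_snps > 0) {
    round(sum(out$length_bp[out$gene_id != "Total"]) / total_snps)
  } else NA_real_
  out
}

coverage_string <- function(annotation) {
  lab <- c(`5UTR` = "5'UTR", exon = "E", intron = "I", `3UTR` = "3'UTR")
  paste(lab[rle(annotation$intervals$region)$values], collapse = "/")
}

#' Run the full analysis pipeline
#'
#' Loads or simulates the study, then runs per-gene site calling, effect
#' classification, diversity and selection statistics, MAF-filtered pairwise
#' LD, the pooled LD-decay fit with the unlinked-SSR threshold and LD
#' extent, SSR diversity summaries, PCoA on DICE distances (genes and SSRs)
#' and AMOVA; writes every table as CSV plus the decay fit as JSON and a run
#' log into `config$outdir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the report bundle (all intermediate objects).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run_log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)
  t_start <- Sys.time()
  logmsg <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    writeLines(line, log_con)
    message(line)
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    logmsg("stage %-12s %.2fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }
  logmsg("popgenld %s | R %s | seed %d | config %s",
         as.character(utils::packageVersion("popgenld")),
         paste(R.version$major, R.version$minor, sep = "."),
         config$seed, config_hash(config))

  study <- stage("load", {
    if (!is.null(config$simulate)) simulate_study(config$simulate)
    else read_study(config$input_dir)
  })

  gene_rows <- stage("genes", lapply(study$alignments, function(aln) {
    sites <- classify_effects(call_sites(aln), aln)
    div <- diversity_summary(aln, sites)
    sel <- tryCatch(dnds(aln, on_stop = "skip"), error = function(e) NULL)
    omega <- if (is.null(sel)) NA_real_ else sel$omega
    sel_p <- if (is.null(sel) || is.na(omega)) NA_real_ else {
      test_neutrality(sel, B = 1000, seed = config$seed)$p
    }
    filtered <- filter_maf(sites, config$maf_threshold)
    ld <- NULL; mean_r2 <- NA_real_
    if (nrow(filtered) >= 2L) {
      am <- allele_matrix(aln, filtered)
      poly <- vapply(seq_len(ncol(am)), function(j) {
        length(unique(am[!is.na(am[, j]), j])) >= 2L
      }, logical(1))
      if (sum(poly) >= 2L) {
        ld <- ld_matrix(am[, poly, drop = FALSE],
                        positions = filtered$pos[poly],
                        genes = rep(aln$gene_id, sum(poly)))
        mean_r2 <- gene_mean_r2(ld)
      }
    }
    ht <- haplotype_table(aln, sites)
    list(gene_id = aln$gene_id, sites = sites, diversity = div,
         coverage = coverage_string(aln$annotation), omega = omega,
         selection_p = sel_p, ld = ld, mean_r2 = mean_r2, haplotypes = ht)
  }))

  gene_table <- summarize_gene_table(gene_rows)
  hap_freqs <- do.call(rbind, lapply(gene_rows, function(g) {
    data.frame(gene_id = g$gene_id, haplotype = g$haplotypes$haplotype,
               count = g$haplotypes$count, freq = g$haplotypes$freq,
               pooled = g$haplotypes$freq < 0.05, stringsAsFactors = FALSE)
  }))
  all_pairs <- do.call(rbind, lapply(gene_rows, function(g) {
    if (is.null(g$ld)) NULL else ld_pairs(g$ld)
  }))

  ssr_res <- stage("ssr", list(
    summary = ssr_summary(study$ssr, config$rarefaction_n,
                          config$bootstrap_B, seed = config$seed),
    loci = ssr_locus_table(study$ssr, config$rarefaction_n,
                           config$bootstrap_B, seed = config$seed),
    r2 = ssr_r2_values(study$ssr)))

  decay <- stage("decay", {
    threshold <- ld_threshold(ssr_res$r2, config$percentile)
    scatter <- if (is.null(all_pairs)) {
      data.frame(distance_bp = numeric(0), r2 = numeric(0))
    } else {
      all_pairs[!is.na(all_pairs$distance_bp) & all_pairs$distance_bp > 0, ]
    }
    n_mean <- round(mean(vapply(gene_rows, function(g) g$diversity$n_lines,
                                numeric(1))))
    if (nrow(scatter) >= 5L) {
      fit <- fit_gamma(data.frame(distance = scatter$distance_bp,
                                  r2 = scatter$r2), n_mean)
      ext <- ld_extent(fit, threshold,
                       d_max = max(vapply(study$alignments,
                                          function(a) ncol(a$seqs), numeric(1))))
      list(fit = fit, threshold_r2 = threshold, extent = ext,
           scatter = scatter, n = n_mean)
    } else {
      logmsg("decay: fewer than 5 within-gene pairs, fit skipped")
      list(fit = NULL, threshold_r2 = threshold, extent = NULL,
           scatter = scatter, n = n_mean)
    }
  })

  struct <- stage("structure", {
    hb <- haplotype_binary(study$alignments, study$populations$line_id)
    sb <- ssr_binary(study$ssr)
    pc_h <- pcoa(1 - dice_matrix(hb))
    pc_s <- pcoa(1 - dice_matrix(sb))
    am <- amova(study$ssr, n_perm = config$amova_perms, seed = config$seed)
    list(pcoa_genes = pc_h, pcoa_ssr = pc_s, amova = am)
  })

  stage("report", {
    wcsv <- function(df, name) {
      utils::write.csv(df, file.path(config$outdir, name), row.names = FALSE,
                       na = "n.a.")
    }
    wcsv(gene_table, "gene_summary.csv")
    wcsv(ssr_res$summary, "ssr_summary.csv")
    wcsv(ssr_res$loci, "ssr_loci.csv")
    wcsv(hap_freqs, "haplotype_freqs.csv")
    if (!is.null(all_pairs)) wcsv(all_pairs, "ld_pairs.csv")
    amv <- struct$amova
    wcsv(data.frame(source = amv$table$source, df = amv$table$df,
                    SSD = amv$table$SSD, MS = amv$table$MS,
                    sigma2 = c(amv$sigma2_among, amv$sigma2_within, NA),
                    pct = c(amv$pct_among, amv$pct_within, 100),
                    phi_st = c(amv$phi_st, NA, NA),
                    p_perm = c(amv$p_perm, NA, NA)), "amova.csv")
    for (what in c("genes", "ssr")) {
      pc <- struct[[paste0("pcoa_", what)]]
      k <- min(4L, ncol(pc$coordinates))
      df <- data.frame(line_id = rownames(pc$coordinates),
                       population = study$populations$population[
                         match(rownames(pc$coordinates),
                               study$populations$line_id)],
                       pc$coordinates[, seq_len(k)])
      wcsv(df, paste0("pcoa_", what, ".csv"))
    }
    dj <- list(threshold_r2 = decay$threshold_r2, n = decay$n)
    if (!is.null(decay$fit)) {
      dj$gamma_per_bp <- decay$fit$gamma_per_bp
      dj$sse <- decay$fit$sse
      dj$n_points <- decay$fit$n_points
      dj$extent_bp <- decay$extent$extent_bp
      dj$extent_status <- decay$extent$status
    }
    jsonlite::write_json(dj, file.path(config$outdir, "decay.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    if (config$plots) {
      try(write_plots(gene_rows, decay, config$outdir), silent = TRUE)
    }
    NULL
  })
  logmsg("done in %.1fs", as.numeric(Sys.time() - t_start, units = "secs"))

  invisible(list(study = study, gene_rows = gene_rows,
                 gene_table = gene_table, haplotype_freqs = hap_freqs,
                 ld_pairs = all_pairs, ssr = ssr_res, decay = decay,
                 structure = struct, config = config))
}

# convenience plots (no analysis depends on them)
write_plots <- function(gene_rows, decay, outdir) {
  for (g in gene_rows) {
    if (is.null(g$ld) || length(g$ld$labels) < 2L) next
    f <- file.path(outdir, paste0("ld_heat_", g$gene_id, ".png"))
    grDevices::png(f, 600, 600)
    r2 <- g$ld$r2
    graphics::image(seq_len(nrow(r2)), seq_len(ncol(r2)), r2,
                    col = grDevices::hcl.colors(25, "YlOrRd", rev = TRUE),
                    xlab = "site", ylab = "site",
                    main = sprintf("%s pairwise r2", g$gene_id))
    grDevices::dev.off()
  }
  if (!is.null(decay$fit) && nrow(decay$scatter)) {
    f <- file.path(outdir, "decay.png")
    grDevices::png(f, 700, 500)
    graphics::plot(decay$scatter$distance_bp, decay$scatter$r2, pch = 20,
                   col = "#00000055", xlab = "distance (bp)", ylab = "r2",
                   main = "LD decay")
    d <- seq(1, max(decay$scatter$distance_bp), length.out = 300)
    graphics::lines(d, hill_weir_expectation(
      decay$fit$gamma_per_bp * d, decay$n), col = "red", lwd = 2)
    graphics::abline(h = decay$threshold_r2, lty = 2)
    grDevices::dev.off()
  }
  invisible(NULL)
}
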