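#' Run the full haplotype-analysis pipeline
#'
#' Orchestrates the package end to end: read/validate inputs, collapse
#' haplotypes, per-population diversity and neutrality summary, mismatch
#' distribution, AMOVA and pairwise Phi-ST (skipped with a logged reason
#' when fewer than two populations have two or more samples), hotspot group
#' assignment and transition-order inference, positional covariance
#' network, G-quadruplex scan, and PCoA of the haplotype distance matrix.
#' Every output file carries a header with the package version, the seed
#' and an md5 hash of the effective configuration; a rerun with identical
#' inputs, seed and configuration produces byte-identical files.
#'
#' @param alignment a [coi_alignment()] or path to a FASTA file.
#' @param pops named character vector or path to a 2-column TSV
#'   (sample id, population); optional.
#' @param out_dir output directory (created if missing).
#' @param key_positions hotspot key sites (default `c(207, 282, 354, 420)`).
#' @param n_perm permutations for AMOVA / pairwise Phi-ST (default 1000).
#' @param seed integer seed controlling all randomness (default 1).
#' @param g4 a [g4_config()].
#' @param graphml also write the covariance network as GraphML?
#' @return Invisibly, a named list with every stage's result.
#' @export
run_pipeline <- function(alignment, pops = NULL, out_dir,
                         key_positions = c(207, 282, 354, 420),
                         n_perm = 1000, seed = 1, g4 = g4_config(),
                         graphml = TRUE) {
  if (is.character(alignment) && length(alignment) == 1)
    alignment <- read_alignment(alignment)
  if (is.character(pops) && length(pops) == 1 && is.null(names(pops)))
    pops <- read_population_map(pops, alignment)
  if (!is.null(pops)) pops <- validate_population_map(pops, alignment)
  if (any(key_positions > alignment$length))
    stop("key positions exceed alignment length")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(version = as.character(utils::packageVersion("coihaps")),
              key_positions = key_positions, n_perm = n_perm, seed = seed,
              g4 = unclass(g4))
  hash <- config_hash(cfg)
  hdr <- sprintf("# coihaps %s | seed=%d | config=%s",
                 cfg$version, seed, hash)
  res <- list(config = cfg, config_hash = hash)
  log_stage <- function(stage, note = "")
    message("[coihaps] ", stage, if (nzchar(note)) paste0(": ", note))

  log_stage("collapse", "haplotype collapsing")
  ht <- collapse_haplotypes(alignment, pops = pops)
  res$haplotypes <- ht
  write_tsv_with_header(as.data.frame(ht), file.path(out_dir, "haplotypes.tsv"), hdr)

  log_stage("diversity", "per-population summary")
  res$diversity <- diversity_summary(alignment, pops)
  write_tsv_with_header(res$diversity, file.path(out_dir, "diversity.tsv"), hdr)

  log_stage("mismatch")
  res$mismatch <- mismatch_distribution(alignment)
  mm <- data.frame(differences = as.integer(names(res$mismatch$histogram)),
                   observed = as.integer(res$mismatch$histogram),
                   expected_constant = res$mismatch$expected_constant,
                   expected_expansion =
                     if (is.null(res$mismatch$expected_expansion)) NA
                     else res$mismatch$expected_expansion)
  mm_hdr <- c(hdr, sprintf("# raggedness=%.6g theta=%.6g tau=%s theta0=%s theta1=%s",
                           res$mismatch$raggedness, res$mismatch$theta,
                           fmt_or_na(res$mismatch$model_params$tau),
                           fmt_or_na(res$mismatch$model_params$theta0),
                           fmt_or_na(res$mismatch$model_params$theta1)))
  write_tsv_with_header(mm, file.path(out_dir, "mismatch.tsv"), mm_hdr)

  amova_ok <- !is.null(pops) && sum(table(pops) >= 2) >= 2
  if (amova_ok) {
    log_stage("amova", sprintf("%d permutations", n_perm))
    res$amova <- amova(alignment, pops, n_perm = n_perm, seed = seed)
    jsonlite::write_json(c(list(seed = seed, config = hash),
                           unclass(res$amova)),
                         file.path(out_dir, "amova.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_stage("pairwise_phist")
    res$pairwise_phist <- pairwise_phist(alignment, pops,
                                         n_perm = n_perm, seed = seed + 1)
    write_tsv_with_header(as.data.frame(res$pairwise_phist$phi_st),
                          file.path(out_dir, "pairwise_phist.tsv"), hdr,
                          row_names = TRUE)
  } else {
    reason <- if (is.null(pops)) "no population map supplied"
              else "fewer than 2 populations with >= 2 samples"
    log_stage("amova", paste("skipped -", reason))
    jsonlite::write_json(list(seed = seed, config = hash, skipped = reason),
                         file.path(out_dir, "amova.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  log_stage("sites", "site classification")
  res$sites <- classify_sites(ht)
  write_tsv_with_header(res$sites, file.path(out_dir, "sites.tsv"), hdr)

  log_stage("groups", paste("key sites", paste(key_positions, collapse = ",")))
  res$groups <- assign_groups(ht, key_positions)
  gdf <- data.frame(hap_id = names(res$groups$assignments),
                    key_string = unname(res$groups$assignments),
                    count = ht$count[match(names(res$groups$assignments),
                                           ht$hap_id)])
  write_tsv_with_header(gdf, file.path(out_dir, "groups.tsv"), hdr)
  res$transition_order <- tryCatch(infer_transition_order(res$groups),
                                   error = function(e) {
                                     log_stage("order", conditionMessage(e))
                                     NULL
                                   })
  if (!is.null(res$transition_order))
    jsonlite::write_json(c(list(seed = seed, config = hash),
                           res$transition_order[c("order", "step_sizes",
                                                  "stepwise")],
                           list(polarity = res$transition_order$polarity)),
                         file.path(out_dir, "transition_order.json"),
                         auto_unbox = TRUE, pretty = TRUE)

  log_stage("covariance")
  pol <- if (!is.null(res$transition_order)) res$transition_order$polarity
  res$covariance <- covariance_network(ht, polarity = pol)
  write_tsv_with_header(res$covariance, file.path(out_dir, "covariance.tsv"), hdr)
  if (graphml)
    write_covariance_graphml(res$covariance,
                             file.path(out_dir, "covariance.graphml"))

  log_stage("g4scan")
  res$g4 <- scan_alignment_hotspots(ht, key_positions, g4)
  write_tsv_with_header(res$g4, file.path(out_dir, "g4_motifs.tsv"), hdr)
  res$g4_summary <- hotspot_g4_summary(res$g4, ht, res$groups)
  write_tsv_with_header(res$g4_summary, file.path(out_dir, "g4_summary.tsv"), hdr)

  log_stage("pcoa", "haplotype distances")
  hd <- pairwise_differences(hap_alignment(ht))$diffs
  res$pcoa <- pcoa(hd)
  pdf_ <- data.frame(hap_id = rownames(res$pcoa$coordinates),
                     res$pcoa$coordinates)
  pc_hdr <- c(hdr, paste0("# explained=",
                          paste(sprintf("%.4f", res$pcoa$explained_fraction),
                                collapse = ",")))
  write_tsv_with_header(pdf_, file.path(out_dir, "pcoa.tsv"), pc_hdr)

  jsonlite::write_json(list(version = cfg$version, seed = seed,
                            config_hash = hash,
                            n_sequences = n_sequences(alignment),
                            n_haplotypes = n_haplotypes(ht),
                            outputs = list.files(out_dir)),
                       file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage("done", out_dir)
  invisible(res)
}

fmt_or_na <- function(x) if (is.null(x)) "NA" else sprintf("%.6g", x)

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)),
             tmp)
  unname(tools::md5sum(tmp))
}

write_tsv_with_header <- function(df, path, header, row_names = FALSE) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = row_names, col.names = TRUE)
  invisible(path)
}
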