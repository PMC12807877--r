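PIPELINE_STAGES <- c("catalog", "occupancy", "counts", "differential",
                     "pauses", "metagene", "enrichment")

#' Load and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent R list) with an
#' `inputs` block (paths: reads, abundance, regions, rna_counts,
#' sample_sheet, and optionally protein, protein_groups, gene_sets, offsets),
#' a `params` block (length_window, frame_threshold, min_mean_reads, alpha,
#' gsea: weight/n_perm/min_size, pause: any [pause_config()] field), a
#' `seed` and an `outdir`. Referenced input paths must exist at run start.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$inputs), !is.null(config$outdir))
  config$seed <- config$seed %||% 1L
  config$params <- config$params %||% list()
  req <- c("reads", "abundance", "regions", "rna_counts", "sample_sheet")
  missing <- setdiff(req, names(config$inputs))
  if (length(missing) > 0) {
    stop("config error: missing inputs: ", paste(missing, collapse = ", "))
  }
  for (nm in names(config$inputs)) {
    if (!file.exists(config$inputs[[nm]])) {
      stop("config error: input file not found: ", nm, " = ", config$inputs[[nm]])
    }
  }
  class(config) <- "pipeline_config"
  config
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  jsonlite::write_json(cfg[sort(names(cfg))], tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

.pause_config_from <- function(params) {
  pc <- params$pause %||% list()
  do.call(pause_config, pc[intersect(names(pc),
                                     names(formals(pause_config)))])
}

#' Run the full positional-translatome pipeline
#'
#' Executes the stages in dependency order (catalog, occupancy profiles, CDS
#' counts, NB differential + TE categories, pause detection/classification,
#' metagene, enrichment concordance), writing every stage's outputs as TSV
#' into `outdir` before the next stage starts, and emits a machine-readable
#' run manifest (JSON: artifact version, config hash, input digests,
#' per-stage status/row counts/wall time, seed) whether the run succeeds or
#' fails.
#'
#' @param config a [pipeline_config()] (or path / list accepted by it).
#' @return invisibly, the manifest list; stage outputs and `manifest.json`
#'   are written under `config$outdir`.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  par <- config$params

  manifest <- list(
    artifact_version = as.character(utils::packageVersion("pausepoint")),
    config_hash = .config_hash(config),
    seed = config$seed,
    inputs = lapply(config$inputs, function(f) unname(tools::md5sum(f))),
    stages = list()
  )
  flush_manifest <- function() {
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }

  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    rows <- tryCatch({
      r <- fun()
      manifest$stages[[name]] <<- list(
        status = "ok", rows = r,
        wall_time_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
      flush_manifest()
      r
    }, error = function(e) {
      manifest$stages[[name]] <<- list(
        status = "failed", error = conditionMessage(e),
        wall_time_s = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
      flush_manifest()
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    invisible(rows)
  }

  run_stage("catalog", function() {
    abundance <- read_abundance(config$inputs$abundance)
    regions <- read_regions(config$inputs$regions)
    state$catalog <- build_catalog(regions, select_mat(abundance, regions))
    write_catalog(state$catalog, p("catalog.tsv"))
    nrow(state$catalog$records)
  })

  run_stage("occupancy", function() {
    reads <- read_read_table(config$inputs$reads)
    state$sample_info <- read_tsv_file(config$inputs$sample_sheet)
    lw <- par$length_window %||% c(27, 38)
    offsets <- if (!is.null(config$inputs$offsets)) {
      ot <- read_tsv_file(config$inputs$offsets)
      fixed_offset_table(ot$length, ot$offset)
    } else {
      calibrate_offsets(reads, state$catalog, length_window = lw,
                        frame_threshold = par$frame_threshold %||% 0.5)
    }
    write_tsv_file(offsets, p("offsets.tsv"))
    state$profiles <- build_profiles(reads, offsets, state$catalog,
                                     state$sample_info)
    write_tsv_file(as.data.frame(state$profiles$counts), p("profiles.tsv"))
    nrow(state$profiles$counts)
  })

  run_stage("counts", function() {
    mmr <- par$min_mean_reads %||% 10
    state$rpf <- cds_count_matrix(state$profiles, min_mean_reads = mmr)
    rna_raw <- read_tsv_file(config$inputs$rna_counts)
    rn <- rna_raw$transcript_id
    m <- as.matrix(rna_raw[, setdiff(names(rna_raw), "transcript_id")])
    rownames(m) <- rn
    state$rna <- count_matrix(filter_min_mean(m, mmr), state$sample_info,
                              assay = "RNA")
    state$rna_unfiltered <- count_matrix(m, state$sample_info, assay = "RNA")
    write_counts_tsv(state$rpf$counts, p("rpf_cds_counts.tsv"))
    write_counts_tsv(state$rna$counts, p("rna_counts_filtered.tsv"))
    nrow(state$rpf$counts)
  })

  run_stage("differential", function() {
    state$de_rpf <- nb_differential(state$rpf)
    state$de_rna <- nb_differential(state$rna)
    write_tsv_file(state$de_rpf, p("de_rpf.tsv"))
    write_tsv_file(state$de_rna, p("de_rna.tsv"))
    state$te <- classify_te(state$de_rna, state$de_rpf,
                            alpha = par$alpha %||% 0.1)
    write_tsv_file(state$te$classes, p("te_classes.tsv"))
    nrow(state$te$classes)
  })

  pc <- .pause_config_from(par)
  run_stage("pauses", function() {
    state$pauses <- find_pause_sites(state$profiles, state$rna_unfiltered, pc)
    write_tsv_file(state$pauses, p("pauses.tsv"))
    dist <- pause_position_distribution(state$pauses, state$catalog)
    write_tsv_file(dist, p("pause_distribution.tsv"))
    nrow(state$pauses)
  })

  run_stage("metagene", function() {
    state$metagene <- metagene_delta(state$profiles, pc)
    write_tsv_file(state$metagene, p("metagene.tsv"))
    nrow(state$metagene)
  })

  run_stage("enrichment", function() {
    if (is.null(config$inputs$gene_sets)) return(0L)
    sets <- read_gmt(config$inputs$gene_sets)
    gp <- par$gsea %||% list()
    rk_rpf <- rpf_ranking(state$de_rpf, state$catalog)
    state$gsea_rpf <- gsea_prerank(rk_rpf, sets,
                                   weight = gp$weight %||% 1,
                                   n_perm = gp$n_perm %||% 10000,
                                   seed = derive_seed(config$seed, 7L),
                                   min_size = gp$min_size %||% 5)
    write_tsv_file(state$gsea_rpf, p("enrichment_rpf.tsv"))
    n <- nrow(state$gsea_rpf)
    if (!is.null(config$inputs$protein)) {
      prot_raw <- read_tsv_file(config$inputs$protein)
      pm <- as.matrix(prot_raw[, setdiff(names(prot_raw), "transcript_id")])
      rownames(pm) <- prot_raw$transcript_id
      rk_prot <- proteome_ranking(pm, state$sample_info)
      state$gsea_prot <- gsea_prerank(rk_prot, sets,
                                      weight = gp$weight %||% 1,
                                      n_perm = gp$n_perm %||% 10000,
                                      seed = derive_seed(config$seed, 8L),
                                      min_size = gp$min_size %||% 5)
      write_tsv_file(state$gsea_prot, p("enrichment_protein.tsv"))
      both <- intersect(state$gsea_rpf$pathway, state$gsea_prot$pathway)
      le <- lapply(both, function(pw) {
        ov <- leading_edge_overlap(state$gsea_rpf, state$gsea_prot, pw)
        data.frame(pathway = pw,
                   shared = ov$counts["shared"],
                   only_rpf = ov$counts["only_rpf"],
                   only_protein = ov$counts["only_protein"],
                   shared_genes = paste(ov$shared, collapse = ","),
                   stringsAsFactors = FALSE)
      })
      write_tsv_file(do.call(rbind, le), p("leading_edge.tsv"))
    }
    n
  })

  flush_manifest()
  invisible(manifest)
}

#' Summarize a completed pipeline run
#'
#' Reads the stage outputs under `outdir` and writes `report.json` and
#' `report.txt` with headline tables: TE category counts, pause counts per
#' class, metagene extrema and top enriched pathways per ranking. Numbers are
#' copied verbatim from the stage outputs; a missing stage output marks its
#' section `"absent"` rather than failing.
#'
#' @param outdir pipeline output directory containing `manifest.json`.
#' @return invisibly, the report list.
#' @export
write_report <- function(outdir) {
  p <- function(f) file.path(outdir, f)
  report <- list(manifest = if (file.exists(p("manifest.json")))
    jsonlite::read_json(p("manifest.json")) else "absent")

  grab <- function(file, fun) {
    if (!file.exists(p(file))) return("absent")
    fun(read_tsv_file(p(file)))
  }
  report$te_category_counts <- grab("te_classes.tsv", function(df) {
    as.list(vapply(TE_CATEGORIES, function(x) sum(df$category == x), integer(1)))
  })
  report$pause_class_counts <- grab("pauses.tsv", function(df) {
    as.list(vapply(c("induced", "resolved", "maintained"),
                   function(x) sum(df$class == x), integer(1)))
  })
  report$metagene_extrema <- grab("metagene.tsv", function(df) {
    lapply(split(df, df$region), function(r) {
      list(max_bin = r$bin[which.max(r$mean_delta)],
           max_delta = max(r$mean_delta, na.rm = TRUE),
           min_bin = r$bin[which.min(r$mean_delta)],
           min_delta = min(r$mean_delta, na.rm = TRUE))
    })
  })
  report$top_pathways <- list(
    rpf = grab("enrichment_rpf.tsv", function(df) {
      df <- df[order(df$pvalue), ][seq_len(min(5, nrow(df))), c("pathway", "nes", "padj")]
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
    }),
    protein = grab("enrichment_protein.tsv", function(df) {
      df <- df[order(df$pvalue), ][seq_len(min(5, nrow(df))), c("pathway", "nes", "padj")]
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
    })
  )

  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  txt <- c("pausepoint run report",
           paste0("  TE categories: ",
                  if (identical(report$te_category_counts, "absent")) "absent"
                  else paste(names(report$te_category_counts),
                             unlist(report$te_category_counts),
                             sep = "=", collapse = ", ")),
           paste0("  pause classes: ",
                  if (identical(report$pause_class_counts, "absent")) "absent"
                  else paste(names(report$pause_class_counts),
                             unlist(report$pause_class_counts),
                             sep = "=", collapse = ", ")))
  writeLines(txt, p("report.txt"))
  invisible(report)
}
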