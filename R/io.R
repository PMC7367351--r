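#' Write a frame stack as a multi-page 16-bit grayscale TIFF
#'
#' @param stack A `frame_stack`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  T_n <- dim(stack$frames)[1]
  lo <- min(stack$frames); hi <- max(stack$frames)
  rng <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(T_n), function(k)
    (stack$frames[k, , ] - lo) / rng)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#'
#' @param path TIFF file (one page per frame, grayscale).
#' @param frame_rate Frames per second of the recording.
#' @return A `frame_stack`.
#' @export
read_stack_tiff <- function(path, frame_rate) {
  stopifnot(file.exists(path), frame_rate > 0)
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  d <- dim(pages[[1]])
  frames <- array(0, dim = c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) frames[k, , ] <- pages[[k]]
  structure(list(frames = frames, frame_interval = 1 / frame_rate),
            class = "frame_stack")
}

#' Read a precomputed correlation trace from CSV
#'
#' @param path CSV with columns `frame`, `value` (comment lines `#` allowed).
#' @param frame_rate Frames per second.
#' @param template_index 1-based template frame index (default: the frame
#'   with the maximum value, which self-correlates as 1).
#' @return A `correlation_trace`.
#' @export
read_trace_csv <- function(path, frame_rate, template_index = NULL) {
  df <- read.csv(path, comment.char = "#")
  stopifnot(all(c("frame", "value") %in% names(df)))
  df <- df[order(df$frame), ]
  ti <- template_index %||% which.max(df$value)
  structure(list(values = df$value, template_index = ti,
                 frame_interval = 1 / frame_rate),
            class = "correlation_trace")
}

#' Write reads as an uncompressed FASTQ file
#'
#' Base qualities are constant `I` (Q40); the caller does not use them.
#'
#' @param reads data.frame with `read_id`, `sequence` (as from
#'   [simulate_amplicon_reads()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- vapply(reads$sequence, function(s)
    strrep("I", nchar(s)), "", USE.NAMES = FALSE)
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path (4-line records).
#' @return data.frame with `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write amplicon references as FASTA
#'
#' @param targets List of [amplicon_target()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_targets_fasta <- function(targets, path) {
  seqs <- Biostrings::DNAStringSet(vapply(targets, `[[`, "", "reference"))
  names(seqs) <- vapply(targets, `[[`, "", "name")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read amplicon target definitions from JSON + FASTA
#'
#' The JSON config holds, per target: `name`, `cut_site` (0-based),
#' `cds_frame_offset`, `strand`, and optionally `blacklist` (array of
#' objects with `pos`, `ref`, `alt`); reference sequences come from the
#' FASTA, matched by name.
#'
#' @param json_path Target config JSON.
#' @param fasta_path Reference FASTA.
#' @return Named list of `amplicon_target` objects.
#' @export
read_targets <- function(json_path, fasta_path) {
  if (!file.exists(json_path)) stop("targets file not found: ", json_path)
  if (!file.exists(fasta_path)) stop("reference FASTA not found: ", fasta_path)
  cfg <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  out <- lapply(cfg, function(tc) {
    if (!tc$name %in% names(seqs))
      stop("no reference sequence for target ", tc$name)
    bl <- NULL
    if (!is.null(tc$blacklist) && length(tc$blacklist)) {
      bl <- do.call(rbind, lapply(tc$blacklist, function(b)
        data.frame(pos = b$pos, ref = b$ref, alt = b$alt,
                   stringsAsFactors = FALSE)))
    }
    amplicon_target(tc$name, as.character(seqs[[tc$name]]), tc$cut_site,
                    tc$cds_frame_offset %||% 0L, tc$strand %||% "+", bl)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Site calls as a VCF-style variant table
#'
#' @param site_calls List of `site_call` objects.
#' @return data.frame with columns `CHROM` (target name), `POS` (1-based),
#'   `REF`, `ALT`, `INFO` (`ALLELE`, `SUPPORT`, `IMPACT`, `WEIGHT`,
#'   `CUTDIST`), one row per called variant per allele.
#' @export
variant_table <- function(site_calls) {
  rows <- list()
  for (sc in site_calls) {
    if (sc$status != "called") next
    for (ai in seq_along(sc$alleles)) {
      v <- sc$alleles[[ai]]$variants
      if (!nrow(v)) next
      for (i in seq_len(nrow(v))) {
        rows[[length(rows) + 1]] <- data.frame(
          CHROM = sc$target, POS = v$pos[i], ID = sc$embryo_id,
          REF = v$ref[i], ALT = v$alt[i],
          INFO = sprintf("ALLELE=%d;SUPPORT=%d;IMPACT=%s;WEIGHT=%s;CUTDIST=%d",
                         ai, sc$alleles[[ai]]$support, v$impact[i],
                         format(v$weight[i]), as.integer(v$cut_distance[i])),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(CHROM = character(0), POS = integer(0), ID = character(0),
                      REF = character(0), ALT = character(0), INFO = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Site calls as a flat CSV-ready table
#'
#' @param site_calls List of `site_call` objects.
#' @return data.frame with `embryo_id`, `target`, `status`, `dosage`.
#' @export
site_call_table <- function(site_calls) {
  do.call(rbind, lapply(site_calls, function(sc)
    data.frame(embryo_id = sc$embryo_id, target = sc$target,
               status = sc$status, dosage = sc$dosage,
               stringsAsFactors = FALSE)))
}

# CSV with a provenance header comment (tool version + config hash)
write_csv_stamped <- function(df, path, config_hash = "none") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# beatcall %s config=%s",
                     as.character(packageVersion("beatcall")), config_hash),
             con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_stamped <- function(path) read.csv(path, comment.char = "#")

#' Pipeline configuration
#'
#' Thresholds default to the screening protocol's values: pause at 3x the
#' median inter-beat interval, arrest at 2 s, a +/- 30 bp cut-site window,
#' at most 2 missing site calls per embryo, impact weights 1/0.66/0.33/0.
#'
#' @param stacks_dir,reads_dir,targets_json,targets_fasta,tables_dir,out_dir
#'   Paths; only the ones a given run needs must exist.
#' @param frame_rate Frames per second of the recordings.
#' @param pause_multiplier,arrest_seconds,cut_window,max_missing Threshold
#'   overrides.
#' @param seed Integer master seed; all stage randomness derives from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(stacks_dir = NULL, reads_dir = NULL,
                            targets_json = NULL, targets_fasta = NULL,
                            tables_dir = NULL, out_dir = "beatcall_out",
                            frame_rate = 152,
                            pause_multiplier = .bc_defaults$pause_multiplier,
                            arrest_seconds = .bc_defaults$arrest_seconds,
                            cut_window = .bc_defaults$cut_window_bp,
                            max_missing = .bc_defaults$max_missing_sites,
                            seed = 1L) {
  structure(list(stacks_dir = stacks_dir, reads_dir = reads_dir,
                 targets_json = targets_json, targets_fasta = targets_fasta,
                 tables_dir = tables_dir, out_dir = out_dir,
                 frame_rate = frame_rate, pause_multiplier = pause_multiplier,
                 arrest_seconds = arrest_seconds, cut_window = cut_window,
                 max_missing = max_missing,
                 impact_weights = .bc_defaults$impact_weights,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# hash of the analysis-relevant configuration (output location excluded, so
# re-running the same analysis elsewhere yields identical stamped outputs)
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the screening pipeline end to end
#'
#' Executes quantify (frame stacks -> cardiac phenotypes), call (amplicon
#' reads -> site calls), dose (missingness rules + imputation) and
#' associate (additive models for HRV, heart rate and sinoatrial pauses),
#' writing per-stage CSVs, a resolved-config JSON, a run manifest and a
#' log under `config$out_dir`. Stacks are read as `<embryo>.tiff` from
#' `stacks_dir`; reads as `<embryo>_<target>.fastq` from `reads_dir`;
#' covariates from `tables_dir/covariates.csv` (columns `embryo_id`,
#' `batch`, `time_of_day`, `experiment`).
#'
#' @param config A [pipeline_config()].
#' @return Path of the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (p in c(config$targets_json, config$targets_fasta))
    if (!is.null(p) && !file.exists(p)) stop("input not found: ", p)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- config_hash(config)
  logf <- file.path(config$out_dir, "run.log")
  cat("", file = logf)
  log_line <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                                "\n", file = logf, append = TRUE)
  stages <- character(0)
  run_stage <- function(name, expr) {
    log_line("stage", name, "start")
    r <- tryCatch(force(expr), error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
    log_line("stage", name, "done")
    stages <<- c(stages, name)
    r
  }
  jsonlite::write_json(unclass(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null")

  # quantify
  pheno <- NULL
  if (!is.null(config$stacks_dir)) {
    pheno <- run_stage("quantify", {
      files <- sort(list.files(config$stacks_dir, "\\.tiff?$", full.names = TRUE))
      if (!length(files)) stop("no TIFF stacks in ", config$stacks_dir)
      rows <- lapply(files, function(fp) {
        id <- sub("\\.tiff?$", "", basename(fp))
        st <- read_stack_tiff(fp, config$frame_rate)
        ph <- quantify_stack(st, pause_multiplier = config$pause_multiplier,
                             arrest_seconds = config$arrest_seconds)
        data.frame(embryo_id = id, n_beats = ph$n_beats,
                   heart_rate_bpm = ph$heart_rate, sdnn_ms = ph$sdnn,
                   rmssd_ms = ph$rmssd, hrv_ms = ph$hrv,
                   has_pause = ph$has_pause, has_arrest = ph$has_arrest,
                   qc_flag = ph$qc_flag, stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
      write_csv_stamped(df, file.path(config$out_dir, "phenotypes.csv"), h)
      df
    })
  }

  # call
  calls_df <- NULL
  site_calls <- NULL
  if (!is.null(config$reads_dir)) {
    site_calls <- run_stage("call", {
      targets <- read_targets(config$targets_json, config$targets_fasta)
      files <- sort(list.files(config$reads_dir, "\\.fastq$", full.names = TRUE))
      if (!length(files)) stop("no FASTQ files in ", config$reads_dir)
      lapply(files, function(fp) {
        base <- sub("\\.fastq$", "", basename(fp))
        parts <- strsplit(base, "_")[[1]]
        tname <- parts[length(parts)]
        eid <- paste(parts[-length(parts)], collapse = "_")
        if (!tname %in% names(targets))
          stop("unknown target '", tname, "' for ", basename(fp))
        call_site(read_fastq(fp), targets[[tname]], embryo_id = eid,
                  cut_window = config$cut_window)
      })
    })
    calls_df <- site_call_table(site_calls)
    write_csv_stamped(calls_df, file.path(config$out_dir, "site_calls.csv"), h)
    write_csv_stamped(variant_table(site_calls),
                      file.path(config$out_dir, "variants.csv"), h)
  }

  # dose
  dosage <- NULL
  if (!is.null(calls_df)) {
    dosage <- run_stage("dose", {
      dm <- assemble_dosage_matrix(calls_df, config$max_missing)
      write_csv_stamped(dm, file.path(config$out_dir, "dosage_matrix.csv"), h)
      dm
    })
  }

  # associate
  if (!is.null(dosage) && !is.null(pheno) && !is.null(config$tables_dir)) {
    run_stage("associate", {
      covar <- read_csv_stamped(file.path(config$tables_dir, "covariates.csv"))
      cohort <- merge(merge(dosage, pheno, by = "embryo_id"),
                      covar, by = "embryo_id")
      ok <- cohort$qc_flag == "ok" & !cohort$has_pause & !cohort$has_arrest
      results <- list()
      for (oc in c("hrv_ms", "heart_rate_bpm")) {
        sub <- cohort[ok & !is.na(cohort[[oc]]), , drop = FALSE]
        if (nrow(sub) >= 10 && length(unique(sub[[oc]])) > 1) {
          sub$y <- inverse_normal(sub[[oc]])
          r <- additive_model("y", sub, "linear")
          r$outcome <- oc
          results[[length(results) + 1]] <- r
        }
      }
      if (sum(cohort$has_pause, na.rm = TRUE) >= 1 &&
          length(unique(cohort$has_pause)) > 1) {
        sub <- cohort[!is.na(cohort$has_pause), , drop = FALSE]
        sub$has_pause <- as.integer(sub$has_pause)
        r <- additive_model("has_pause", sub, "logistic")
        r$outcome <- "has_pause"
        results[[length(results) + 1]] <- r
      }
      res <- do.call(rbind, results)
      write_csv_stamped(res, file.path(config$out_dir, "associations.csv"), h)
      res
    })
  }

  manifest <- list(tool = "beatcall",
                   version = as.character(packageVersion("beatcall")),
                   seed = config$seed, config_hash = h,
                   stages_completed = as.list(stages))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$out_dir)
}
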