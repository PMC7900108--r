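# Readers and writers: square matrix files, node-label lists, subject
# metadata, long-format result tables, and flat key-value run configs.

sniff_sep <- function(line) {
  if (grepl("\t", line)) "\t" else if (grepl(",", line)) "," else ""
}

#' Read a connectivity matrix file
#'
#' Square numeric matrix as CSV, TSV or whitespace-delimited text
#' (delimiter sniffed from the first line), with an optional single
#' header row of node labels.  The matrix is validated as a
#' [connectome].
#'
#' @param path File path.
#' @param node_labels Optional label vector overriding any header.
#' @param subject_id Subject identifier (default: file name stem).
#' @return A [connectome].
#' @export
read_connectome_matrix <- function(path, node_labels = NULL,
                                   subject_id = NULL) {
  if (!file.exists(path)) abort(sprintf("matrix file not found: %s", path))
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  first <- readLines(path, n = 1)
  sep <- sniff_sep(first)
  tokens <- strsplit(trimws(first),
                     if (sep == "") "[[:space:]]+" else sep)[[1]]
  header <- anyNA(suppressWarnings(as.numeric(tokens)))
  m <- as.matrix(utils::read.table(path, sep = sep, header = header,
                                   check.names = FALSE))
  if (header && is.null(node_labels)) node_labels <- colnames(m)
  rownames(m) <- NULL
  connectome(m, node_labels = node_labels, subject_id = subject_id)
}

#' Read a node-label file
#'
#' One label per line; order defines the node index.
#'
#' @param path File path.
#' @return Character vector of labels.
#' @export
read_node_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("label file not found: %s", path))
  labs <- trimws(readLines(path))
  labs[nzchar(labs)]
}

#' Load a study directory
#'
#' Reads the subject metadata table (CSV with `subject_id`, `group`,
#' `age`, `sex`, `education` and any additional columns as cognitive
#' scores), one matrix file `<subject_id>.csv` per subject from
#' `matrix_dir`, and an optional node-label file.  Subjects are aligned
#' in a canonical order (sorted by id) so downstream results do not
#' depend on metadata row order.  Validation problems are aggregated and
#' reported together with the offending subject ids.
#'
#' @param matrix_dir Directory of matrix files.
#' @param metadata_csv Path of the subject metadata CSV.
#' @param labels_file Optional node-label file applied to every matrix.
#' @return List with `connectomes` (list of [connectome]), `design`
#'   (tibble of subject_id, group and covariates) and `scores` (tibble
#'   of subject_id plus score columns, or NULL if none).
#' @export
load_study <- function(matrix_dir, metadata_csv, labels_file = NULL) {
  if (!file.exists(metadata_csv)) {
    abort(sprintf("metadata file not found: %s", metadata_csv))
  }
  meta <- readr::read_csv(metadata_csv, show_col_types = FALSE)
  needed <- c("subject_id", "group", "age", "sex", "education")
  if (!all(needed %in% names(meta))) {
    abort(paste0("metadata must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  meta <- arrange(meta, .data$subject_id)
  labels <- if (!is.null(labels_file)) read_node_labels(labels_file)

  files <- list.files(matrix_dir, pattern = "\\.(csv|tsv|txt)$")
  stems <- sub("\\.[^.]*$", "", files)
  missing <- setdiff(meta$subject_id, stems)
  extra <- setdiff(stems, meta$subject_id)
  problems <- character(0)
  if (length(missing) > 0) {
    problems <- c(problems, paste0("no matrix file for subject(s): ",
                                   paste(missing, collapse = ", ")))
  }
  if (length(extra) > 0) {
    problems <- c(problems, paste0("matrix file(s) without metadata: ",
                                   paste(extra, collapse = ", ")))
  }
  conns <- list()
  if (length(missing) == 0) {
    for (sid in meta$subject_id) {
      f <- file.path(matrix_dir, files[match(sid, stems)])
      conn <- tryCatch(
        read_connectome_matrix(f, node_labels = labels, subject_id = sid),
        error = function(e) conditionMessage(e)
      )
      if (is.character(conn)) {
        problems <- c(problems, sprintf("subject %s: %s", sid, conn))
      } else {
        conns[[sid]] <- conn
      }
    }
  }
  if (length(problems) > 0) {
    abort(paste0("study validation failed:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  ns <- vapply(conns, n_nodes, integer(1))
  if (length(unique(ns)) > 1) {
    abort("matrices have inconsistent node counts across subjects.")
  }
  score_cols <- setdiff(names(meta), needed)
  list(
    connectomes = unname(conns),
    design = validate_design(meta[, needed], min_per_group = 1),
    scores = if (length(score_cols) > 0) {
      meta[, c("subject_id", score_cols)]
    }
  )
}

#' Write a long-format metric table
#'
#' TSV with columns `subject_id`, `scope`, `measure`, `node_label`
#' (empty for global rows) and `value`.
#'
#' @param metrics Tibble from [connectome_metrics()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  out <- metrics %>%
    rename(node_label = "node") %>%
    mutate(node_label = ifelse(is.na(.data$node_label), "",
                               .data$node_label))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write group-comparison results
#'
#' TSV with one row per feature and the post-hoc contrasts flattened
#' into per-contrast columns, plus a sidecar `<path>.meta` key-value
#' file carrying the run metadata (seed, permutation count, scheme).
#'
#' @param results Tibble from [run_nodal_group_analysis()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_group_results_tsv <- function(results, path) {
  flat <- results %>% select(-"posthoc") %>%
    rename(node_label = "node") %>%
    mutate(node_label = ifelse(is.na(.data$node_label), "",
                               .data$node_label))
  ph <- purrr::map(results$posthoc, function(p) {
    if (is.null(p)) return(tibble(.rows = 1))
    wide <- list()
    for (i in seq_len(nrow(p))) {
      key <- gsub("[^A-Za-z0-9]+", "_", p$contrast[i])
      wide[[paste0("f_", key)]] <- p$f[i]
      wide[[paste0("p_perm_", key)]] <- p$p_perm[i]
      wide[[paste0("p_fdr_", key)]] <- p$p_fdr[i]
    }
    as_tibble(wide)
  }) %>% bind_rows()
  readr::write_tsv(dplyr::bind_cols(flat, ph), path)
  meta <- attr(results, "run_meta")
  if (!is.null(meta)) {
    write_flat_config(meta, paste0(path, ".meta"))
  }
  invisible(path)
}

#' Write correlation results
#'
#' Long-format TSV mirroring the published correlation tables: one row
#' per (group, score, measure, node) with `r`, `p`, `p_fdr` and the
#' effective n.
#'
#' @param results Tibble from [run_correlation_analysis()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_correlations_tsv <- function(results, path) {
  out <- results %>%
    rename(node_label = "node") %>%
    mutate(node_label = ifelse(is.na(.data$node_label), "",
                               .data$node_label))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Flat key-value configuration files
#'
#' `write_flat_config()` serializes a named list of scalars as
#' `key = value` lines; `read_flat_config()` parses them back (numbers
#' become numeric).
#'
#' @param config Named list of scalar values.
#' @param path File path.
#' @return The config (read) or `path` invisibly (write).
#' @export
write_flat_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, paste(format(config[[k]]), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_flat_config
#' @export
read_flat_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) abort(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a synthetic study to a directory
#'
#' One matrix CSV per subject (header row of node labels), a
#' `metadata.csv` with covariates and scores, and a `ground_truth.txt`
#' flat key-value ledger of the planted effects.
#'
#' @param cohort A `synthetic_cohort` with connectomes.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(cohort, dir) {
  if (is.null(cohort$connectomes)) abort("cohort has no connectomes.")
  dir.create(file.path(dir, "matrices"), recursive = TRUE,
             showWarnings = FALSE)
  for (conn in cohort$connectomes) {
    utils::write.table(
      conn$weights, file.path(dir, "matrices",
                              paste0(conn$subject_id, ".csv")),
      sep = ",", row.names = FALSE, col.names = conn$node_labels
    )
  }
  readr::write_csv(cohort$subjects, file.path(dir, "metadata.csv"))
  gt <- cohort$ground_truth
  flat <- list(clip_rate = gt$clip_rate %||% 0)
  eff <- gt$effects
  if (!is.null(eff) && nrow(eff) > 0) {
    for (i in seq_len(nrow(eff))) {
      flat[[sprintf("effect_%d", i)]] <-
        sprintf("%s|%s|%g", eff$node[i], eff$group[i], eff$size[i])
    }
  }
  for (nm in names(gt$score_links)) {
    sl <- gt$score_links[[nm]]
    flat[[paste0("score_link_", nm)]] <-
      sprintf("%s|%s|%s|r=%g|beta=%g", sl$measure,
              if (is.na(sl$node %||% NA)) "" else sl$node,
              sl$group, sl$r, sl$beta)
  }
  write_flat_config(flat, file.path(dir, "ground_truth.txt"))
  invisible(dir)
}
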