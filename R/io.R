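# File formats: volumes and atlases are NIfTI; persistence pairs, landscapes
# and cohort tables are CSV; the atlas lookup is TSV; grids and replication
# reports are JSON. Voxel indices are 1-based inside R and 0-based on disk.

#' Read / write a 3D volume as NIfTI
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume`: a plain 3D array.
#' @export
read_volume <- function(path) {
  v <- RNifti::readNifti(path)
  a <- array(as.numeric(v), dim = dim(v))
  a
}

#' @rdname read_volume
#' @param vol 3D numeric array.
#' @export
write_volume <- function(vol, path) {
  validate_volume(vol)
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  invisible(path)
}

#' Read / write a label atlas (NIfTI labels + TSV lookup)
#' @param labels_path NIfTI path for the integer label volume.
#' @param lookup_path TSV path with columns label, name, hemisphere.
#' @return `read_atlas`: a list with `labels` and `lookup`.
#' @export
read_atlas <- function(labels_path, lookup_path) {
  labels <- read_volume(labels_path)
  storage.mode(labels) <- "integer"
  lookup <- read.delim(lookup_path, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "name", "hemisphere") %in% names(lookup)))
  missing <- setdiff(unique(labels[labels != 0L]), lookup$label)
  if (length(missing) > 0L) {
    stop_validation(sprintf("labels missing from lookup: %s",
                            paste(missing, collapse = ", ")))
  }
  list(labels = labels, lookup = lookup)
}

#' @rdname read_atlas
#' @param atlas list with `labels` and `lookup`.
#' @export
write_atlas <- function(atlas, labels_path, lookup_path) {
  write_volume(atlas$labels + 0, labels_path)
  write.table(atlas$lookup, lookup_path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(labels_path)
}

#' Read / write persistence pairs as CSV
#'
#' Columns: participant_id, scope, birth, death, peak_i, peak_j, peak_k,
#' roi. Peak indices are written 0-based on disk.
#'
#' @param pairs pairs data.frame; `participant_id`/`scope` columns are
#'   added from the arguments if absent.
#' @param path CSV path.
#' @param participant_id,scope identifiers recorded with the pairs.
#' @export
write_pairs_csv <- function(pairs, path, participant_id = "", scope = "") {
  out <- data.frame(participant_id = participant_id, scope = scope,
                    birth = pairs$birth, death = pairs$death,
                    peak_i = pairs$peak_i - 1L, peak_j = pairs$peak_j - 1L,
                    peak_k = pairs$peak_k - 1L,
                    roi = ifelse(is.na(pairs$roi), 0L, pairs$roi),
                    stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pairs_csv
#' @export
read_pairs_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  d$peak_i <- d$peak_i + 1L
  d$peak_j <- d$peak_j + 1L
  d$peak_k <- d$peak_k + 1L
  d$roi <- ifelse(d$roi == 0L, NA_integer_, as.integer(d$roi))
  d
}

#' Write landscapes as wide CSV plus a JSON grid sidecar
#'
#' @param landscapes named list of [landscape_first()] vectors on one grid.
#' @param path CSV path (`pos_1..pos_G` columns); the sidecar is written to
#'   `paste0(path, ".grid.json")`.
#' @param scope scope label stored in the CSV.
#' @export
write_landscapes_csv <- function(landscapes, path, scope = "") {
  grid <- attr(landscapes[[1]], "grid")
  m <- do.call(rbind, landscapes)
  out <- data.frame(participant_id = names(landscapes), scope = scope,
                    m, stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- paste0("pos_", seq_len(grid$G))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(lo = grid$lo, hi = grid$hi, G = grid$G),
                       paste0(path, ".grid.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write position-wise analysis results as TSV
#' @param results data.frame from [analyze_scope()] / [run_pipeline()].
#' @param path TSV path.
#' @export
write_results_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a replication report as JSON
#' @param pipeline result of [run_pipeline()].
#' @param path JSON path.
#' @export
write_report_json <- function(pipeline, path) {
  rep <- lapply(pipeline$report, function(g) {
    list(positive = g$positive, negative = g$negative,
         k_star_a = g$k_star_a, k_star_b = g$k_star_b,
         headline = g$headline)
  })
  jsonlite::write_json(list(scopes = rep, headline = pipeline$headline,
                            alpha = pipeline$config$alpha,
                            n_perm = pipeline$config$n_perm,
                            seed = pipeline$config$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a cohort table as CSV
#'
#' Header: id, decoding, word_id, comprehension, rapid_naming, verbal_comp,
#' age, sex, site, total_brain_volume. Empty cells are missing values.
#'
#' @param table cohort table.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE,
           colClasses = c(id = "character"), na.strings = "")
}
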