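# Delimited-text readers/writers.  Matrices travel as TSV (square, header
# row of node ids; sessions have one row per timepoint) with a JSON
# sidecar (<path>.json) carrying metadata: module map, seeds, generation
# parameters, estimator and hyperparameter.

write_matrix_tsv <- function(m, path, col_names = NULL) {
  m <- as.matrix(m)
  colnames(m) <- col_names %||% paste0("n", seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              check.names = FALSE))
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a ground-truth network
#'
#' The weight matrix goes to `path` as a square TSV; the module map,
#' inhibitory module and generation parameters go to a `<path>.json`
#' sidecar so a read round-trips the full object.
#'
#' @param net An [fc_network][generate_network].
#' @param path File path for the weight matrix.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns an `fc_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "fc_network"))
  write_matrix_tsv(net$weights, path)
  jsonlite::write_json(
    list(type = "fc_network", module = net$module,
         inhibitory_module = net$inhibitory_module, meta = net$meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  w <- unname(read_matrix_tsv(path))
  structure(list(weights = w, module = meta$module,
                 inhibitory_module = meta$inhibitory_module,
                 meta = as.list(meta$meta)),
            class = "fc_network")
}

#' Write / read an activity session
#'
#' Timepoints-by-nodes TSV with a header row of node ids; sampling
#' metadata (noise level, seed, TR) goes to the JSON sidecar.
#'
#' @param session An `fc_session`.
#' @param path File path.
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   an `fc_session`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "fc_session"))
  write_matrix_tsv(session$data, path)
  jsonlite::write_json(
    list(type = "fc_session", noise_level = session$noise_level,
         seed = session$seed, tr = session$tr,
         network_seed = session$network_seed),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  structure(list(data = unname(read_matrix_tsv(path)),
                 noise_level = meta$noise_level, seed = meta$seed,
                 tr = meta$tr, network_seed = meta$network_seed),
            class = "fc_session")
}

#' Write / read an FC matrix
#'
#' Square TSV plus JSON sidecar with method, hyperparameter, source and
#' solver diagnostics.
#'
#' @param fc An [fc_matrix].
#' @param path File path.
#' @return `write_fc()` returns `path` invisibly; `read_fc()` an
#'   [fc_matrix].
#' @export
write_fc <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  write_matrix_tsv(fc_values(fc), path)
  jsonlite::write_json(
    list(type = "fc_matrix", method = attr(fc, "method"),
         hyperparameter = attr(fc, "hyperparameter"),
         source = attr(fc, "source"),
         diagnostics = attr(fc, "diagnostics")),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_fc
#' @export
read_fc <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  fc_matrix(unname(read_matrix_tsv(path)), method = meta$method,
            hyperparameter = meta$hyperparameter, source = meta$source,
            diagnostics = meta$diagnostics)
}

#' Write / read a synthetic cohort
#'
#' One directory: `covariates.tsv`, one FC file per subject
#' (`fc_<id>.tsv` + sidecar) and `cohort.json` with the planted-effect
#' record.
#'
#' @param cohort An [fc_cohort][generate_cohort].
#' @param dir Directory path (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` an
#'   `fc_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in seq_along(cohort$fc)) {
    write_fc(cohort$fc[[s]], file.path(dir, sprintf("fc_%04d.tsv", s)))
  }
  jsonlite::write_json(list(type = "fc_cohort",
                            planted = unclass(cohort$planted),
                            meta = cohort$meta),
                       file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  info <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = TRUE)
  cov <- tibble::as_tibble(utils::read.table(
    file.path(dir, "covariates.tsv"), sep = "\t", header = TRUE))
  fc <- lapply(seq_len(nrow(cov)), function(s) {
    read_fc(file.path(dir, sprintf("fc_%04d.tsv", s)))
  })
  structure(list(fc = fc, covariates = cov,
                 planted = as.list(info$planted), meta = as.list(info$meta)),
            class = "fc_cohort")
}
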