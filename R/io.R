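# File formats and the umbrella pipeline: plain-text CSV for tables, labeled
# TSV (plus a long-format CSV) for dyadic matrices, YAML for configuration,
# JSON for results.

#' Read an attribute table CSV
#'
#' Expected columns: id, sex, age, reproductive_status, mother_id (empty for
#' unknown); extra columns are kept.
#'
#' @param path CSV file.
#' @return data.frame with mother_id as character (NA when empty).
#' @export
read_attributes <- function(path) {
  at <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(mother_id = "character"))
  required <- c("id", "sex", "age", "reproductive_status")
  miss <- setdiff(required, names(at))
  if (length(miss) > 0) {
    stop("attribute table is missing columns: ",
         paste(miss, collapse = ", "))
  }
  if (anyDuplicated(at$id)) {
    stop("duplicate ids in attribute table")
  }
  if (any(!at$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  if (any(at$age < 0, na.rm = TRUE)) {
    stop("ages must be nonnegative")
  }
  bad <- at$sex == "male" & at$reproductive_status != "not_applicable"
  if (any(bad)) {
    stop("males must have reproductive_status 'not_applicable'")
  }
  if ("mother_id" %in% names(at)) {
    at$mother_id[!nzchar(at$mother_id)] <- NA_character_
  } else {
    at$mother_id <- NA_character_
  }
  at
}

#' @rdname read_attributes
#' @param attrs attribute table to write.
#' @export
write_attributes <- function(attrs, path) {
  out <- attrs
  out$mother_id[is.na(out$mother_id)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the scans and events CSVs
#'
#' Scans: follow_id, focal_id, scan_index, time_min, party_members,
#' within10_members (semicolon-joined). Events: event_id, time_s, signaller,
#' recipients, gesture_label, modality, context, sequence_hint,
#' response_present, response_category.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_scans <- function(path) {
  sc <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(party_members = "character",
                                       within10_members = "character"))
  required <- c("follow_id", "focal_id", "scan_index", "time_min",
                "party_members", "within10_members")
  miss <- setdiff(required, names(sc))
  if (length(miss) > 0) {
    stop("scans table is missing columns: ", paste(miss, collapse = ", "))
  }
  sc
}

#' @rdname read_scans
#' @param scans scan table to write.
#' @export
write_scans <- function(scans, path) {
  utils::write.csv(scans, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_scans
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("time_s", "signaller", "recipients", "context")
  miss <- setdiff(required, names(ev))
  if (length(miss) > 0) {
    stop("events table is missing columns: ", paste(miss, collapse = ", "))
  }
  ev
}

#' @rdname read_scans
#' @param events event table to write.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write coded sequences as CSV (list columns are flattened)
#'
#' @param sequences sequence table from \code{\link{segment_sequences}}.
#' @param path CSV file.
#' @export
write_sequences <- function(sequences, path) {
  out <- sequences
  if ("gaps" %in% names(out)) {
    out$gaps <- vapply(out$gaps, function(g) paste(signif(g, 10),
                                                   collapse = ";"),
                       character(1))
  }
  if ("event_ids" %in% names(out)) {
    out$event_ids <- vapply(out$event_ids, paste, character(1),
                            collapse = ";")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a dyadic matrix as labeled TSV
#'
#' The first row and first column carry the node labels; values are written
#' with 15 significant digits so a write/read round trip preserves labels
#' exactly and values to at least 12 significant digits. A long-format CSV
#' (from, to, value) can be written alongside for tabular tooling.
#'
#' @param path TSV file.
#' @param zero_diagonal how to treat a nonzero diagonal on read; see
#'   \code{\link{dyad_matrix}}.
#' @return a \code{\link{dyad_matrix}}.
#' @export
read_dyad_matrix <- function(path, zero_diagonal = "warn") {
  lines <- readLines(path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    stop("ragged rows in matrix file ", path)
  }
  header <- fields[[1]][-1]
  body <- fields[-1]
  row_labels <- vapply(body, `[`, character(1), 1)
  if (anyDuplicated(header) || anyDuplicated(row_labels)) {
    stop("duplicate labels in matrix file ", path)
  }
  if (!identical(header, row_labels)) {
    stop("row labels do not match column header in ", path)
  }
  vals <- t(vapply(body, function(f) as.numeric(f[-1]),
                   numeric(length(header))))
  if (length(header) == 1) {
    vals <- matrix(as.numeric(body[[1]][-1]), 1, 1)
  }
  dimnames(vals) <- list(row_labels, header)
  name <- sub("\\.[^.]*$", "", basename(path))
  dyad_matrix(vals, name = name, zero_diagonal = zero_diagonal)
}

#' @rdname read_dyad_matrix
#' @param m matrix to write.
#' @param long_path optional path for the long-format CSV companion.
#' @export
write_dyad_matrix <- function(m, path, long_path = NULL) {
  m <- as_dyad_matrix(m)
  labs <- rownames(m)
  vals <- as.matrix(m)
  lines <- c(paste(c("", labs), collapse = "\t"),
             vapply(seq_along(labs), function(i) {
               paste(c(labs[i], formatC(vals[i, ], format = "g",
                                        digits = 15)),
                     collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  if (!is.null(long_path)) {
    idx <- offdiag_index(length(labs))
    long <- data.frame(from = labs[idx$row], to = labs[idx$col],
                       value = vals[cbind(idx$row, idx$col)])
    utils::write.csv(long, long_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Assemble (or load) a pipeline configuration
#'
#' A pipeline run is configured either by a synthetic generator block or by
#' paths to real attribute/scan/event CSVs -- exactly one of the two. Coder,
#' build and inference options have package defaults.
#'
#' @param x a list, or a path to a YAML file, with elements:
#'   \code{synthetic} (arguments for \code{\link{synthetic_config}}) or
#'   \code{paths} (attrs, scans, events); optional \code{coder}
#'   (strict_wait_window), \code{build} (drop_zero_exposure, scan_interval),
#'   \code{inference} (n_perm, seed, exhaustive_limit), \code{out_dir}.
#' @return validated config list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(x) {
  if (is.character(x) && length(x) == 1) {
    x <- yaml::read_yaml(x)
  }
  stopifnot(is.list(x))
  has_syn <- !is.null(x$synthetic)
  has_paths <- !is.null(x$paths)
  if (has_syn == has_paths) {
    stop("exactly one of 'synthetic' and 'paths' must be configured")
  }
  cfg <- list(
    synthetic = if (has_syn) do.call(synthetic_config, x$synthetic),
    paths = x$paths,
    coder = utils::modifyList(list(strict_wait_window = FALSE),
                              x$coder %||% list()),
    build = utils::modifyList(list(drop_zero_exposure = FALSE,
                                   scan_interval = 2),
                              x$build %||% list()),
    inference = utils::modifyList(list(n_perm = 2000L, seed = NULL,
                                       exhaustive_limit = 5040),
                                  x$inference %||% list()),
    out_dir = x$out_dir %||% NULL)
  if (cfg$inference$n_perm < 1) {
    stop("n_perm must be at least 1")
  }
  if (has_paths) {
    miss <- setdiff(c("attrs", "scans", "events"), names(cfg$paths))
    if (length(miss) > 0) {
      stop("paths block is missing: ", paste(miss, collapse = ", "))
    }
  }
  if (has_syn) {
    cfg$build$scan_interval <- cfg$synthetic$scan_interval
  }
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[gestnet:%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline: simulate/load, code, build, model
#'
#' Chains the stages end to end: obtain attributes, scans and events (from
#' the synthetic generator or from files), segment and classify sequences,
#' build all dyadic matrices, fit the six dyadic hypothesis models and the
#' node-level centrality model. When \code{out_dir} is set, every artifact
#' is written there: input tables and coded sequences as CSV, every matrix
#' as labeled TSV plus long CSV, model results and a run log (seed,
#' permutation count, node/dyad counts, per-class sequence counts) as JSON.
#'
#' @param config a \code{\link{pipeline_config}}, or anything it accepts.
#' @return (invisibly) list with data, sequences, networks, mrqap results,
#'   node regression result, and the run log.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) {
    config
  } else {
    pipeline_config(config)
  }
  if (!is.null(cfg$synthetic)) {
    pipeline_log("simulate", "generating synthetic study (seed %s)",
                 cfg$synthetic$seed %||% "none")
    data <- simulate_gesture_study(cfg$synthetic)
  } else {
    pipeline_log("load", "reading %s", cfg$paths$attrs)
    data <- list(attrs = read_attributes(cfg$paths$attrs),
                 scans = read_scans(cfg$paths$scans),
                 events = read_events(cfg$paths$events))
  }

  pipeline_log("code", "segmenting %d events", nrow(data$events))
  sequences <- segment_sequences(
    data$events, strict_wait_window = cfg$coder$strict_wait_window)
  cls_counts <- table(factor(sequences$cls, levels = sequence_classes()))

  pipeline_log("build", "tallying %d scans, %d sequences",
               nrow(data$scans), nrow(sequences))
  networks <- build_networks(data$attrs, data$scans, sequences,
                             scan_interval = cfg$build$scan_interval,
                             drop_zero_exposure =
                               cfg$build$drop_zero_exposure)
  mask <- attr(networks, "mask")

  inf <- cfg$inference
  seeds <- split_seed(inf$seed, 2)
  pipeline_log("mrqap", "fitting 6 dyadic models, %d permutations",
               inf$n_perm)
  mrqap <- run_hypothesis_models(networks, n_perm = inf$n_perm,
                                 seed = seeds[[1]], mask = mask)
  pipeline_log("nodereg", "fitting node-level centrality model")
  nodereg <- run_centrality_model(networks, data$attrs, n_perm = inf$n_perm,
                              seed = seeds[[2]],
                              exhaustive_limit = inf$exhaustive_limit)

  log <- list(seed = inf$seed,
              n_perm = inf$n_perm,
              n_nodes = nrow(data$attrs),
              n_dyads = nrow(data$attrs) * (nrow(data$attrs) - 1),
              n_scans = nrow(data$scans),
              n_events = nrow(data$events),
              sequence_counts = as.list(cls_counts),
              excluded_sequences = networks$tallies$excluded_sequences)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- cfg$out_dir
    write_attributes(data$attrs, file.path(od, "attributes.csv"))
    write_scans(data$scans, file.path(od, "scans.csv"))
    write_events(data$events, file.path(od, "events.csv"))
    write_sequences(sequences, file.path(od, "sequences.csv"))
    for (nm in setdiff(names(networks), "tallies")) {
      write_dyad_matrix(networks[[nm]],
                        file.path(od, paste0(nm, ".tsv")),
                        long_path = file.path(od, paste0(nm, "_long.csv")))
    }
    results <- list(mrqap = lapply(mrqap, unclass),
                    node_regression = unclass(nodereg),
                    log = log)
    jsonlite::write_json(results, file.path(od, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(c(utils::capture.output(for (r in mrqap) print(r)),
                 utils::capture.output(print(nodereg))),
               file.path(od, "results.txt"))
    pipeline_log("write", "artifacts in %s", od)
  }

  invisible(list(data = data, sequences = sequences, networks = networks,
                 mrqap = mrqap, node_regression = nodereg, log = log))
}
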