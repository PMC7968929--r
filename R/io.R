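# 32-bit FNV-1a hash of a string, as 8 hex digits. Used to stamp artifacts
# with the configuration they came from.
fnv1a32 <- function(text) {
  bytes <- utf8ToInt(enc2utf8(text))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply in exact double arithmetic (16-bit split)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

#' Run configuration
#'
#' Bundles every knob of a pipeline run — model parameters, grids,
#' thresholds, readout parameters, seed — into one serializable object, so a
#' run is reproducible from its config alone.
#'
#' @param params A [model_params()].
#' @param readout A [readout_params()].
#' @param K_grid,mu_grid Search grids, defaults from [default_grids()].
#' @param tau Model classification threshold.
#' @param fold Experimental fold threshold.
#' @param seed Integer seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(params = model_params(),
                       readout = readout_params(),
                       K_grid = default_grids()$K,
                       mu_grid = default_grids()$mu,
                       tau = params$tau, fold = 3, seed = 1L) {
  structure(list(params = unclass(params), readout = unclass(readout),
                 K_grid = K_grid, mu_grid = mu_grid, tau = tau,
                 fold = fold, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @return `config_json`: canonical JSON text; `config_hash`: an 8-hex-digit
#'   stamp of it.
#' @export
config_json <- function(config) {
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
}

#' @rdname run_config
#' @export
config_hash <- function(config) {
  fnv1a32(as.character(config_json(config)))
}

# Writes a data frame as CSV with '#'-prefixed header lines carrying the
# config hash; floats at 10 significant digits for cross-platform stability.
write_stamped_csv <- function(df, path, config = NULL, extra_header = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(paste0("# config_hash: ", config_hash(config)), con)
  }
  if (!is.null(extra_header)) writeLines(paste0("# ", extra_header), con)
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_stamped_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read and write arrangement specification files
#'
#' Tab-separated files with columns `label`, `junction1_name`,
#' `junction1_mu`, `junction2_name`, `junction2_mu` (`NA` mu = inherit the
#' model mu). Reading validates each label and reports the offending token
#' of a malformed one.
#'
#' @param path File path.
#' @return `read_arrangements`: a list of [arrangement()] objects.
#' @export
read_arrangements <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "junction1_name", "junction1_mu", "junction2_name",
            "junction2_mu")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("arrangement file misses column(s): ", paste(miss, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    a <- parse_label(df$label[i])
    a$junctions <- list(
      terminator(df$junction1_name[i], df$junction1_mu[i]),
      terminator(df$junction2_name[i], df$junction2_mu[i]))
    a
  })
}

#' @rdname read_arrangements
#' @param arrangements List of [arrangement()] objects.
#' @export
write_arrangements <- function(arrangements, path) {
  df <- do.call(rbind, lapply(arrangements, function(a) {
    data.frame(label = a$label,
               junction1_name = a$junctions[[1]]$name,
               junction1_mu = a$junctions[[1]]$readthrough_rate,
               junction2_name = a$junctions[[2]]$name,
               junction2_mu = a$junctions[[2]]$readthrough_rate,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write observed phenotype tables
#'
#' CSV with columns `label` and `phenotype` (extra columns pass through).
#' Reading validates arrangement labels — naming the offending token — and
#' rejects duplicate labels. Mixed line endings are tolerated.
#'
#' @param path File path.
#' @return A data frame with at least `label` and `phenotype`.
#' @export
read_observed <- function(path) {
  df <- read_stamped_csv(path)
  if (!all(c("label", "phenotype") %in% names(df))) {
    stop("observed table needs columns 'label' and 'phenotype'")
  }
  for (l in df$label) parse_label(l)   # errors name the bad token
  if (anyDuplicated(df$label)) {
    stop("duplicate arrangement label: ",
         df$label[duplicated(df$label)][1])
  }
  df
}

#' @rdname read_observed
#' @param observed Data frame with `label`, `phenotype`.
#' @param config Optional [run_config()] to stamp into the header.
#' @export
write_observed <- function(observed, path, config = NULL) {
  write_stamped_csv(observed, path, config)
}

#' Read and write measurement tables
#'
#' CSV serialization of [generate_measurements()] output.
#'
#' @param path File path.
#' @param measurements Measurement data frame.
#' @param config Optional [run_config()] stamped into the header.
#' @export
write_measurements <- function(measurements, path, config = NULL) {
  write_stamped_csv(measurements, path, config)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  df <- read_stamped_csv(path)
  need <- c("label", "condition", "replicate", "fluorescence")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("measurement table misses column(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(df$fluorescence <= 0)) stop("fluorescence must be positive")
  df
}

#' Serialize a grid-search result
#'
#' Long-format CSV (`K`, `mu`, `agreement`, `admissible`) plus an optional
#' JSON summary of the admissible cells.
#'
#' @param grid_result A `grid_result` from [grid_search()].
#' @param path CSV path.
#' @param json_path Optional path for the JSON argmax summary.
#' @param config Optional [run_config()] stamped into the header.
#' @export
write_grid <- function(grid_result, path, json_path = NULL, config = NULL) {
  long <- expand.grid(K = grid_result$K_grid, mu = grid_result$mu_grid,
                      KEEP.OUT.ATTRS = FALSE)
  long$agreement <- as.vector(grid_result$agreement)
  long$admissible <- as.vector(grid_result$admissible)
  write_stamped_csv(long, path, config)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(max_agreement = grid_result$max_agreement,
           n_observed = grid_result$n_observed,
           argmax = grid_result$argmax),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  df <- read_stamped_csv(path)
  K_grid <- sort(unique(df$K))
  mu_grid <- sort(unique(df$mu))
  agreement <- matrix(df$agreement[order(match(df$mu, mu_grid),
                                         match(df$K, K_grid))],
                      length(K_grid), length(mu_grid))
  admissible <- agreement == max(agreement)
  idx <- which(admissible, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  structure(list(K_grid = K_grid, mu_grid = mu_grid, agreement = agreement,
                 admissible = admissible, max_agreement = max(agreement),
                 n_observed = NA_integer_,
                 argmax = data.frame(K = K_grid[idx[, 1]],
                                     mu = mu_grid[idx[, 2]],
                                     agreement = agreement[idx])),
            class = "grid_result")
}
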