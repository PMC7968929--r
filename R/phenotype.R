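# Named logic classes over the canonical state order (none, IPTG, aTc,
# both); ON = TRUE. Patterns without a field name render as e.g.
# "ON-OFF-ON-OFF".
LOGIC_NAMES <- c(
  "1111" = "ALL_ON",
  "0000" = "ALL_OFF",
  "1000" = "NOR",
  "1100" = "NOT_aTc",
  "1010" = "NOT_IPTG"
)

bits_to_key <- function(bits) paste(as.integer(bits), collapse = "")

#' Convert between ON/OFF patterns and logic labels
#'
#' The mapping is bijective over the 16 four-state patterns. Five patterns
#' carry conventional gate names (`ALL_ON`, `ALL_OFF`, `NOR`, `NOT_aTc`,
#' `NOT_IPTG`); the rest render as explicit patterns such as
#' `"ON-OFF-ON-OFF"`. States are always ordered (none, IPTG, aTc, both).
#'
#' @param bits Logical (or 0/1) vector of length 4; `TRUE` = ON.
#' @return `logic_name`: a label string; `logic_bits`: a logical vector.
#' @export
logic_name <- function(bits) {
  stopifnot(length(bits) == 4L)
  bits <- as.logical(bits)
  key <- bits_to_key(bits)
  if (key %in% names(LOGIC_NAMES)) return(unname(LOGIC_NAMES[key]))
  paste(ifelse(bits, "ON", "OFF"), collapse = "-")
}

#' @rdname logic_name
#' @param label A label produced by `logic_name` (named or pattern form).
#' @export
logic_bits <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  hit <- match(label, LOGIC_NAMES)
  if (!is.na(hit)) {
    key <- names(LOGIC_NAMES)[hit]
    return(strsplit(key, "")[[1]] == "1")
  }
  parts <- strsplit(label, "-", fixed = TRUE)[[1]]
  if (length(parts) != 4L || !all(parts %in% c("ON", "OFF"))) {
    stop("unknown logic label: '", label, "'")
  }
  parts == "ON"
}

#' Classify a model cI vector into a logic phenotype
#'
#' Steady-state cI values over the four canonical states are normalized by
#' their maximum; a state is ON when its normalized cI lies below the
#' threshold `tau` (the output promoter P_R is repressed by CI, so low cI
#' means high output). A degenerate all-zero vector (no repressor output at
#' all) classifies as `ALL_ON`.
#'
#' @param c_values Numeric vector of 4 non-negative cI values in canonical
#'   state order (none, IPTG, aTc, both).
#' @param tau Threshold on normalized cI, in (0, 1).
#' @return A logic label string (see [logic_name()]).
#' @export
classify_model <- function(c_values, tau = 2 / 5) {
  stopifnot(length(c_values) == 4L)
  if (any(c_values < 0)) stop("cI values must be non-negative")
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  m <- max(c_values)
  if (m < 1e-12) return(logic_name(rep(TRUE, 4L)))
  logic_name(c_values / m < tau)
}

#' Classify replicate-mean fluorescence values into a logic phenotype
#'
#' Implements the two threefold rules used for experimental phenotype calls:
#' a state is OFF when it shows at least threefold repression relative to the
#' highest state (ON set = values above `max/fold`), and the call is only
#' accepted when the minimal ON value is at least `fold` times the maximal
#' OFF value; otherwise the strain is `AMBIGUOUS`. With no OFF state the
#' phenotype is `ALL_ON`. The rule uses ratios only, so it is invariant to
#' rescaling.
#'
#' @param yfp_means Numeric vector of 4 positive fluorescence means in
#'   canonical state order.
#' @param fold Fold threshold (default 3).
#' @return A logic label string, possibly `"AMBIGUOUS"`.
#' @export
classify_experimental <- function(yfp_means, fold = 3) {
  stopifnot(length(yfp_means) == 4L, fold > 1)
  if (any(yfp_means <= 0)) stop("fluorescence values must be positive")
  on <- yfp_means > max(yfp_means) / fold
  if (all(on)) return(logic_name(rep(TRUE, 4L)))
  if (min(yfp_means[on]) < fold * max(yfp_means[!on])) return("AMBIGUOUS")
  logic_name(on)
}

#' Distribution of logic labels as the model threshold varies
#'
#' Classifies every arrangement's cI vector at each threshold and tallies the
#' labels, reproducing a varying-threshold sweep of the model phenotypes.
#'
#' @param c_vectors A named list (or 4-column matrix with rownames) of cI
#'   vectors per arrangement.
#' @param taus Thresholds in (0, 1).
#' @return Tidy data frame (`tau`, `label`, `count`).
#' @export
threshold_sweep <- function(c_vectors, taus) {
  if (is.matrix(c_vectors)) {
    c_vectors <- split(c_vectors, row(c_vectors))
  }
  stopifnot(all(taus > 0), all(taus < 1))
  out <- lapply(taus, function(tau) {
    labels <- vapply(c_vectors, classify_model, character(1), tau = tau)
    tab <- table(labels)
    data.frame(tau = tau, label = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Distribution of experimental labels as the fold threshold varies
#'
#' Companion sweep to [threshold_sweep()] for the experimental classifier:
#' tallies [classify_experimental()] labels over a grid of fold thresholds.
#'
#' @param value_matrix Named list (or matrix) of positive 4-vectors per
#'   strain.
#' @param folds Fold thresholds, all > 1.
#' @return Tidy data frame (`fold`, `label`, `count`).
#' @export
fold_sweep <- function(value_matrix, folds) {
  if (is.matrix(value_matrix)) {
    value_matrix <- split(value_matrix, row(value_matrix))
  }
  stopifnot(all(folds > 1))
  out <- lapply(folds, function(fd) {
    labels <- vapply(value_matrix, classify_experimental, character(1),
                     fold = fd)
    tab <- table(labels)
    data.frame(fold = fd, label = names(tab), count = as.integer(tab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
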