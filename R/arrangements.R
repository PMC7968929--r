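#' @keywords internal
"_PACKAGE"

# Fixed wiring of the cassette: each repressor gene, the promoter driving it,
# and the repressor acting on that promoter. The topology never varies; only
# the order and orientation of the three transcriptional units do.
GENES <- c(L = "lacI", T = "tetR", C = "cI")

#' Transcriptional-unit wiring table
#'
#' Returns the fixed gene -> promoter -> repressor -> inducer mapping of the
#' three-repressor cassette: `lacI` and `tetR` are both driven by P_lac
#' (repressed by LacI, induced by IPTG = input I1), `cI` is driven by P_tet
#' (repressed by TetR, induced by aTc = input I2).
#'
#' @return A data frame with columns `gene`, `promoter`, `repressed_by`,
#'   `inducer`.
#' @export
tu_wiring <- function() {
  data.frame(
    gene         = c("lacI", "tetR", "cI"),
    promoter     = c("P_lac", "P_lac", "P_tet"),
    repressed_by = c("lacI", "lacI", "tetR"),
    inducer      = c("I1", "I1", "I2"),
    stringsAsFactors = FALSE
  )
}

#' Terminator specification for a junction between two transcriptional units
#'
#' A junction terminator is described by its name and the fraction of RNA
#' polymerase reading through it. `readthrough_rate = NA` means "use the
#' model's global read-through rate mu" (the default T1 junction, whose rate
#' is the free parameter of the model).
#'
#' @param name Terminator name, e.g. `"T1"`, `"T1T2"`, `"Tcrp"`, `"TtonB"`.
#' @param readthrough_rate Fraction in \[0, 1\] of transcription reading
#'   through, or `NA` to inherit the model parameter `mu`.
#' @return An object of class `terminator_spec`.
#' @export
terminator <- function(name = "T1", readthrough_rate = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  readthrough_rate <- as.numeric(readthrough_rate)
  stopifnot(length(readthrough_rate) == 1L)
  if (!is.na(readthrough_rate) &&
      (readthrough_rate < 0 || readthrough_rate > 1)) {
    stop("readthrough_rate must lie in [0, 1], got ", readthrough_rate)
  }
  structure(list(name = name, readthrough_rate = readthrough_rate),
            class = "terminator_spec")
}

#' Combine two terminators placed at the same junction
#'
#' Read-through probabilities of tandem terminators multiply: a polymerase
#' must read through both to reach the downstream unit.
#'
#' @param spec1,spec2 `terminator_spec` objects. `NA` rates are resolved
#'   against `mu` before multiplying.
#' @param mu Global read-through rate used to resolve `NA` rates.
#' @return A `terminator_spec` whose rate is the product of the two rates.
#' @export
double_terminator <- function(spec1, spec2, mu = NULL) {
  stopifnot(inherits(spec1, "terminator_spec"),
            inherits(spec2, "terminator_spec"))
  r1 <- spec1$readthrough_rate
  r2 <- spec2$readthrough_rate
  if (is.na(r1) || is.na(r2)) {
    if (is.null(mu)) stop("mu needed to resolve an NA readthrough_rate")
    if (is.na(r1)) r1 <- mu
    if (is.na(r2)) r2 <- mu
  }
  terminator(paste0(spec1$name, spec2$name), r1 * r2)
}

new_arrangement <- function(slots, junctions, label) {
  structure(list(slots = slots, junctions = junctions, label = label),
            class = "arrangement")
}

validate_arrangement <- function(a) {
  stopifnot(inherits(a, "arrangement"))
  if (nrow(a$slots) != 3L || !setequal(a$slots$gene, GENES)) {
    stop("arrangement must contain each of lacI, tetR, cI exactly once")
  }
  if (!all(a$slots$orientation %in% c("forward", "reverse"))) {
    stop("orientation must be 'forward' or 'reverse'")
  }
  if (length(a$junctions) != 2L) stop("arrangement needs exactly 2 junctions")
  invisible(a)
}

#' Construct an arrangement of the three-repressor cassette
#'
#' An arrangement is an ordered triple of (gene, orientation) slots, read left
#' to right along the cassette, with a terminator at each of the two internal
#' junctions. The cassette is a linear segment: there is no wraparound
#' adjacency to the plasmid backbone.
#'
#' @param genes Character vector of the three genes in slot order
#'   (`"lacI"`, `"tetR"`, `"cI"` in any order, each once).
#' @param orientations Character vector (`"forward"`/`"reverse"`), recycled to
#'   length 3.
#' @param junctions List of two [terminator()] specs (slot 1-2 and slot 2-3);
#'   default two T1 terminators inheriting the model mu.
#' @return An object of class `arrangement`.
#' @export
arrangement <- function(genes, orientations = "forward",
                        junctions = list(terminator(), terminator())) {
  orientations <- rep_len(orientations, 3L)
  slots <- data.frame(gene = as.character(genes),
                      orientation = as.character(orientations),
                      stringsAsFactors = FALSE)
  a <- new_arrangement(slots, junctions, label = NA_character_)
  validate_arrangement(a)
  a$label <- format_label(a)
  a
}

#' @export
print.arrangement <- function(x, ...) {
  cat("<arrangement> ", x$label, "\n", sep = "")
  jn <- vapply(x$junctions, function(j) {
    if (is.na(j$readthrough_rate)) paste0(j$name, " (mu)")
    else paste0(j$name, " (", signif(j$readthrough_rate, 3), ")")
  }, character(1))
  cat("  junctions: ", paste(jn, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Enumerate slot assignments for an arbitrary gene set; generalized helper
# behind enumerate_arrangements (n! orders x 2^n orientation patterns).
enumerate_slot_sets <- function(genes, allow_reverse = TRUE) {
  n <- length(genes)
  perm_rows <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_rows(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  orders <- perm_rows(sort(genes))
  oris <- if (allow_reverse) {
    expand.grid(rep(list(c("forward", "reverse")), n),
                stringsAsFactors = FALSE)
  } else {
    as.data.frame(matrix("forward", 1L, n), stringsAsFactors = FALSE)
  }
  out <- list()
  for (ord in orders) {
    for (r in seq_len(nrow(oris))) {
      out[[length(out) + 1L]] <-
        data.frame(gene = ord, orientation = unlist(oris[r, ], use.names = FALSE),
                   stringsAsFactors = FALSE)
    }
  }
  out
}

#' Enumerate all order/orientation permutations of the cassette
#'
#' Every gene in every slot, each gene exactly once, both orientations per
#' slot when `allow_reverse = TRUE`: 3! * 2^3 = 48 arrangements, or the 6
#' all-forward orders otherwise. The list order is deterministic
#' (lexicographic in gene order, then orientation patterns with forward
#' first).
#'
#' @param allow_reverse Include reverse-orientation slots?
#' @return List of [arrangement()] objects, all with default T1 junctions.
#' @export
enumerate_arrangements <- function(allow_reverse = TRUE) {
  sets <- enumerate_slot_sets(unname(GENES), allow_reverse)
  lapply(sets, function(s) arrangement(s$gene, s$orientation))
}

#' Reverse a whole cassette relative to the backbone
#'
#' The flip of an arrangement reverses the slot order, inverts every
#' orientation, and reverses the junction list. In a backbone-free model an
#' arrangement and its flip are indistinguishable.
#'
#' @param a An [arrangement()].
#' @return The flipped `arrangement`.
#' @export
flip_arrangement <- function(a) {
  validate_arrangement(a)
  slots <- a$slots[3:1, , drop = FALSE]
  rownames(slots) <- NULL
  slots$orientation <- ifelse(slots$orientation == "forward",
                              "reverse", "forward")
  out <- new_arrangement(slots, rev(a$junctions), NA_character_)
  out$label <- format_label(out)
  out
}

#' Partition the full enumeration into orientation pairs
#'
#' Pairs every arrangement with its whole-cassette flip. The input must be
#' closed under flipping (e.g. the full 48-element enumeration, which
#' partitions into 24 pairs).
#'
#' @param arrangements List of [arrangement()] objects closed under
#'   [flip_arrangement()].
#' @return List of pairs; each element is a list of two arrangements, in input
#'   order of their first member.
#' @export
orientation_pairs <- function(arrangements) {
  labels <- vapply(arrangements, function(a) a$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate arrangements in input")
  flips <- vapply(arrangements, function(a) flip_arrangement(a)$label,
                  character(1))
  if (!all(flips %in% labels)) {
    stop("input is not closed under flipping; missing: ",
         paste(setdiff(flips, labels), collapse = ", "))
  }
  seen <- character(0)
  pairs <- list()
  for (i in seq_along(arrangements)) {
    if (labels[i] %in% seen) next
    j <- match(flips[i], labels)
    if (j == i) stop("arrangement is its own flip: ", labels[i])
    pairs[[length(pairs) + 1L]] <- list(arrangements[[i]], arrangements[[j]])
    seen <- c(seen, labels[i], labels[j])
  }
  pairs
}

#' Canonical pair identifier for an arrangement
#'
#' The lexicographically smaller of the arrangement's label and its flip's
#' label, shared by both members of an orientation pair.
#'
#' @param a An [arrangement()].
#' @return Character pair id.
#' @export
pair_id <- function(a) {
  min(a$label, flip_arrangement(a)$label)
}

#' Parse and format arrangement labels
#'
#' Labels use one letter per slot, left to right: `C` = cI, `L` = lacI,
#' `T` = tetR, with an `_r` suffix marking reverse orientation, e.g. `"TLC"`
#' or `"LT_rC_r"`. `parse_label` and `format_label` are mutually inverse on
#' valid labels; parsed arrangements carry default T1 junctions.
#'
#' @param text A label string.
#' @return `parse_label`: an [arrangement()]; `format_label`: a string.
#' @export
parse_label <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tokens <- regmatches(text, gregexpr("[A-Za-z0-9]_r|[A-Za-z0-9]", text))[[1]]
  if (paste(tokens, collapse = "") != text || length(tokens) != 3L) {
    stop("malformed arrangement label: '", text, "'")
  }
  letters3 <- substr(tokens, 1L, 1L)
  bad <- setdiff(letters3, names(GENES))
  if (length(bad)) {
    stop("unknown gene letter '", bad[1], "' in label '", text, "'")
  }
  if (anyDuplicated(letters3)) {
    stop("duplicate gene letter '", letters3[duplicated(letters3)][1],
         "' in label '", text, "'")
  }
  arrangement(genes = unname(GENES[letters3]),
              orientations = ifelse(endsWith(tokens, "_r"),
                                    "reverse", "forward"))
}

#' @rdname parse_label
#' @param a An [arrangement()].
#' @export
format_label <- function(a) {
  stopifnot(inherits(a, "arrangement"))
  letters3 <- names(GENES)[match(a$slots$gene, GENES)]
  paste0(letters3,
         ifelse(a$slots$orientation == "reverse", "_r", ""),
         collapse = "")
}
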