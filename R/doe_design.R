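# Taguchi L9(3^4) orthogonal-array construction and validation.

# Canonical run -> level-index assignment for the packaged co-digestion study.
# Row order is the study's layout, not the textbook L9 order.
.l9_levels <- matrix(
  c(1, 1, 1, 1,
    2, 1, 2, 3,
    2, 2, 3, 1,
    1, 2, 2, 2,
    3, 3, 2, 1,
    3, 2, 1, 3,
    1, 3, 3, 3,
    2, 3, 1, 2,
    3, 1, 3, 2),
  ncol = 4, byrow = TRUE,
  dimnames = list(NULL, c("A", "B", "C", "D"))
)

#' Describe one experimental factor with its three levels
#'
#' A factor is identified by a single-letter label and carries exactly three
#' physical level values. The level order is the assignment order of the
#' design, not a sorted order: level indices ("A2", "C3", ...) refer to
#' positions in `levels`, so a non-monotone sequence such as sonication times
#' of 15, 30, 0 min is legitimate (level 3 = 0 min, the untreated control).
#'
#' @param name Single-letter factor label, e.g. `"A"`.
#' @param description Free-text description of the physical quantity.
#' @param levels Numeric vector of exactly 3 distinct physical values.
#' @param units Unit string for the physical values.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("C", "sonication time", c(15, 30, 0), "min")
#' @export
factor_spec <- function(name, description, levels, units = "") {
  stopifnot(is.character(name), length(name) == 1L, nchar(name) >= 1L)
  if (length(levels) != 3L || anyDuplicated(levels) || !is.numeric(levels)) {
    stop("a factor requires exactly three distinct numeric levels",
         call. = FALSE)
  }
  structure(
    list(name = name, description = description,
         levels = as.numeric(levels), units = units),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("%s: %s (%s) levels: %s\n", x$name, x$description, x$units,
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' The co-digestion study's factor set
#'
#' Loads the packaged factor table: A = oil-refinery wastewater (ORWW)
#' portion in the digester (%), B = process temperature (deg C),
#' C = sonication pretreatment time (min; level 3 is the 0-min control),
#' D = total-solids level in the digester (%).
#'
#' @return A list of four [factor_spec()] objects named A-D.
#' @export
codigestion_factors <- function() {
  path <- system.file("extdata", "factor_levels.csv", package = "codigest",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    factor_spec(tab$factor[i], tab$description[i],
                c(tab$level1[i], tab$level2[i], tab$level3[i]), tab$units[i])
  })
  names(specs) <- tab$factor
  specs
}

#' Build the L9(3^4) orthogonal array for four three-level factors
#'
#' Returns the nine-run balanced design in the canonical row order of the
#' packaged study: each factor column holds each level index exactly three
#' times, and every ordered pair of levels occurs exactly once for every
#' pair of columns. Nine runs cover the four-factor main effects that a
#' full factorial would need 81 runs for.
#'
#' @param factors List of exactly four [factor_spec()] objects.
#' @return A data frame of class `l9_design` with columns `run_id`, one
#'   level-index column per factor (`A_level`, ...), and `designation`.
#' @examples
#' d <- build_l9(codigestion_factors())
#' validate_design(d)
#' @export
build_l9 <- function(factors = codigestion_factors()) {
  if (length(factors) != 4L || !all(vapply(factors, inherits, logical(1),
                                           "factor_spec"))) {
    stop("build_l9() requires exactly four factor_spec objects",
         call. = FALSE)
  }
  letters4 <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(letters4)) {
    stop("factor names must be distinct", call. = FALSE)
  }
  design <- data.frame(run_id = 1:9)
  for (j in 1:4) design[[paste0(letters4[j], "_level")]] <- .l9_levels[, j]
  design$designation <- apply(.l9_levels, 1L, function(lv) {
    designation(lv, letters4)
  })
  structure(design, class = c("l9_design", "data.frame"),
            factors = factors)
}

#' Check balance and pairwise orthogonality of a design
#'
#' Validates by exhaustive counting: every level index appears exactly three
#' times per column, and all nine ordered level pairs occur exactly once for
#' each of the six column pairs.
#'
#' @param design An `l9_design` or a data frame with `*_level` columns.
#' @return `TRUE` invisibly; otherwise an error describing the violation.
#' @export
validate_design <- function(design) {
  lev <- design_levels(design)
  if (nrow(lev) != 9L || ncol(lev) != 4L) {
    stop("an L9 design must have 9 runs and 4 level columns", call. = FALSE)
  }
  if (!all(lev %in% 1:3)) {
    stop("level indices must lie in 1..3", call. = FALSE)
  }
  for (j in seq_len(ncol(lev))) {
    counts <- tabulate(lev[, j], nbins = 3L)
    if (any(counts != 3L)) {
      stop(sprintf("column %s is unbalanced: level counts %s",
                   colnames(lev)[j], paste(counts, collapse = "/")),
           call. = FALSE)
    }
  }
  for (j in 1:3) {
    for (k in (j + 1):4) {
      pair_id <- paste(lev[, j], lev[, k])
      if (anyDuplicated(pair_id)) {
        stop(sprintf("columns %s and %s are not orthogonal",
                     colnames(lev)[j], colnames(lev)[k]), call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

# Extract the 9 x 4 level-index matrix from a design data frame.
design_levels <- function(design) {
  cols <- grep("_level$", names(design), value = TRUE)
  as.matrix(design[, cols, drop = FALSE])
}

#' Render a formulation designation string
#'
#' A formulation (one level index per factor) is named by concatenating the
#' factor letter and its level index, e.g. levels (2, 1, 2, 1) give
#' `"A2B1C2D1"`.
#'
#' @param levels Integer vector of level indices, one per factor, each in 1..3.
#' @param factor_names Factor letters, by default A-D.
#' @return The designation string.
#' @examples
#' designation(c(2, 1, 2, 1))  # "A2B1C2D1"
#' @export
designation <- function(levels, factor_names = c("A", "B", "C", "D")) {
  levels <- as.integer(levels)
  if (length(levels) != length(factor_names) ||
      any(levels < 1L | levels > 3L)) {
    stop("level indices must be in 1..3, one per factor", call. = FALSE)
  }
  paste0(factor_names, levels, collapse = "")
}

#' Parse a designation string back to level indices
#'
#' Inverse of [designation()]: `"A2B1C2D1"` gives `c(A = 2, B = 1, C = 2,
#' D = 1)`.
#'
#' @param text Designation string such as `"A2B1C2D1"`.
#' @return Named integer vector of level indices.
#' @export
parse_designation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- gregexpr("[A-Z][0-9]", text)[[1]]
  parts <- regmatches(text, list(m))[[1]]
  if (length(parts) == 0L ||
      nchar(text) != sum(nchar(parts))) {
    stop(sprintf("malformed designation '%s'", text), call. = FALSE)
  }
  lv <- as.integer(substr(parts, 2L, 2L))
  names(lv) <- substr(parts, 1L, 1L)
  if (any(lv < 1L | lv > 3L)) {
    stop(sprintf("level index out of range in '%s'", text), call. = FALSE)
  }
  lv
}

#' Resolve a run's level indices to physical factor values
#'
#' @param design An `l9_design` built by [build_l9()].
#' @param run Run id in 1..9.
#' @return Named numeric vector of physical values (units as in the factor
#'   specs), e.g. run 3 of the packaged design resolves to 44% ORWW,
#'   46 deg C, 0 min sonication, 6% TS.
#' @export
physical_values <- function(design, run) {
  if (!run %in% design$run_id) {
    stop(sprintf("unknown run id %s", run), call. = FALSE)
  }
  factors <- attr(design, "factors")
  if (is.null(factors)) {
    stop("design carries no factor specifications", call. = FALSE)
  }
  lev <- design_levels(design)[design$run_id == run, ]
  out <- vapply(seq_along(factors), function(j) {
    factors[[j]]$levels[lev[j]]
  }, numeric(1))
  names(out) <- vapply(factors, `[[`, character(1), "name")
  out
}
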