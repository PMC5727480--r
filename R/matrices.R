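#' Discrete morphological character matrix
#'
#' Builds the container used throughout the package for discrete (cladistic)
#' characters. Each cell is a set of integer states: a singleton for an
#' ordinary scoring, several states for a polymorphic scoring, and `NA` for
#' missing data (`?`). Inapplicable scorings (`-`) are treated as missing,
#' since none of the downstream methods distinguish them.
#'
#' @param states a list-matrix (taxa x characters) whose `[[i, j]]` element is
#'   an integer vector of states, or `NA` for missing. A plain character
#'   matrix of cells such as `"0"`, `"{01}"`, `"?"` is also accepted and
#'   parsed.
#' @param taxa character vector of taxon names; defaults to
#'   `rownames(states)`.
#' @param ordering per-character vector, `"unordered"` or `"ordered"`;
#'   recycled if length 1.
#' @return an object of class `discrete_matrix` with elements `taxa`,
#'   `states` (list-matrix), `ordering` and `nchar`.
#' @examples
#' m <- discrete_matrix(rbind(A = c("0", "1"), B = c("1", "?")))
#' m$states[[2, 2]]  # NA: missing
#' @export
discrete_matrix <- function(states, taxa = rownames(states),
                            ordering = "unordered") {
  force(taxa)
  if (is.character(states)) {
    cells <- states
    states <- matrix(vector("list", length(cells)), nrow(cells), ncol(cells))
    for (i in seq_len(nrow(cells))) {
      for (j in seq_len(ncol(cells))) {
        states[[i, j]] <- parse_discrete_cell(cells[i, j])
      }
    }
  }
  if (!is.matrix(states) || !is.list(states))
    stop("`states` must be a list-matrix or character matrix")
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(states)))
  nchar <- ncol(states)
  ordering <- rep_len(ordering, nchar)
  obj <- structure(
    list(taxa = as.character(taxa), states = states,
         ordering = ordering, nchar = nchar),
    class = "discrete_matrix")
  validate_discrete_matrix(obj)
  obj
}

parse_discrete_cell <- function(cell) {
  cell <- gsub("[[:space:]]", "", cell)
  if (cell %in% c("?", "-", "")) return(NA_integer_)
  body <- sub("^[[{(]", "", sub("[]})]$", "", cell))
  chars <- strsplit(body, "")[[1]]
  st <- suppressWarnings(as.integer(chars))
  # letters A.. for states 10.. (TNT/NEXUS extended symbols)
  alpha <- is.na(st) & grepl("[A-Za-z]", chars)
  st[alpha] <- match(toupper(chars[alpha]), LETTERS) + 9L
  if (anyNA(st)) stop("unreadable discrete cell: '", cell, "'")
  sort(unique(st))
}

validate_discrete_matrix <- function(m) {
  if (anyDuplicated(m$taxa)) stop("duplicate taxon names in matrix")
  if (nrow(m$states) != length(m$taxa))
    stop("taxon count does not match matrix rows")
  if (ncol(m$states) != m$nchar) stop("nchar does not match matrix columns")
  bad <- vapply(m$states, function(x) length(x) == 0L, logical(1))
  if (any(bad)) stop("empty state set in matrix cell")
  invisible(m)
}

#' @export
print.discrete_matrix <- function(x, ...) {
  cat("Discrete character matrix:", length(x$taxa), "taxa x", x$nchar,
      "characters\n")
  cat("Missing cells:", sum(vapply(x$states, cell_is_missing, logical(1))),
      " Polymorphic cells:",
      sum(vapply(x$states, function(s) length(s) > 1L, logical(1))), "\n")
  invisible(x)
}

cell_is_missing <- function(x) length(x) == 1L && is.na(x[1])

#' Proportion of missing cells in a character matrix
#'
#' @param m a `discrete_matrix` or `continuous_matrix`.
#' @return fraction of cells flagged missing.
#' @export
missing_fraction <- function(m) {
  if (inherits(m, "discrete_matrix"))
    mean(vapply(m$states, cell_is_missing, logical(1)))
  else mean(is.na(unclass(m)))
}

#' Continuous (morphometric ratio) character matrix
#'
#' Continuous characters are a-dimensional ratios, so non-missing values must
#' be strictly positive; `NA` marks missing.
#'
#' @param values numeric matrix, taxa in rows (rownames) x characters in
#'   columns.
#' @param taxa optional taxon names overriding rownames.
#' @return a numeric matrix of class `continuous_matrix`.
#' @export
continuous_matrix <- function(values, taxa = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(values)))
  if (anyDuplicated(taxa)) stop("duplicate taxon names in matrix")
  rownames(values) <- taxa
  if (any(values <= 0, na.rm = TRUE))
    stop("continuous ratio characters must be strictly positive")
  class(values) <- c("continuous_matrix", class(matrix()))
  values
}

#' @export
print.continuous_matrix <- function(x, ...) {
  cat("Continuous character matrix:", nrow(x), "taxa x", ncol(x),
      "characters (", sum(is.na(x)), "missing cells )\n")
  invisible(x)
}

#' Taxon stratigraphic ranges and diets
#'
#' @param name taxon names (must be unique).
#' @param fad first appearance datum, Ma (older = larger).
#' @param lad last appearance datum, Ma; `fad >= lad > 0` is enforced.
#' @param diet one of `"carnivore"`, `"omnivore"`, `"herbivore"`,
#'   `"unknown"`; empty or `NA` becomes `"unknown"`.
#' @return data.frame of class `taxon_records`.
#' @export
taxon_records <- function(name, fad, lad, diet = "unknown") {
  diet <- as.character(diet)
  diet[is.na(diet) | diet == ""] <- "unknown"
  ok <- diet %in% c("carnivore", "omnivore", "herbivore", "unknown")
  if (!all(ok)) stop("unknown diet label: ", paste(diet[!ok], collapse = ", "))
  fad <- as.numeric(fad); lad <- as.numeric(lad)
  if (anyNA(fad) || anyNA(lad)) stop("non-numeric taxon ages")
  if (anyDuplicated(name)) stop("duplicate taxon names")
  bad <- fad < lad
  if (any(bad))
    stop("fad < lad for: ", paste(name[bad], collapse = ", "))
  if (any(lad <= 0)) stop("ages must be positive (Ma before present)")
  structure(
    data.frame(name = as.character(name), fad = fad, lad = lad, diet = diet,
               stringsAsFactors = FALSE),
    class = c("taxon_records", "data.frame"))
}
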