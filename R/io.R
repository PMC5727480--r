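#' Read a NEXUS character matrix
#'
#' Parses the `CHARACTERS`/`DATA` block of a NEXUS file into a
#' [discrete_matrix()] (DATATYPE=STANDARD) or [continuous_matrix()]
#' (DATATYPE=CONTINUOUS). Polymorphic cells written as `{01}` or `(01)`
#' become state sets; `?` and `-` become missing. Cells that cannot be
#' interpreted raise an error rather than being silently treated as missing.
#'
#' @param path path to a NEXUS file.
#' @return a `discrete_matrix` or `continuous_matrix`, depending on the
#'   block's DATATYPE.
#' @export
read_nexus <- function(path) {
  txt <- strip_nexus_comments(paste(readLines(path, warn = FALSE),
                                    collapse = "\n"))
  if (!grepl("#NEXUS", txt, ignore.case = TRUE))
    stop("not a NEXUS file (missing #NEXUS header): ", path)
  block <- extract_nexus_block(txt, c("CHARACTERS", "DATA"))
  if (is.null(block)) stop("no CHARACTERS or DATA block in ", path)
  dims <- nexus_keyvals(block, "DIMENSIONS")
  ntax <- as.integer(dims[["NTAX"]])
  nchar <- as.integer(dims[["NCHAR"]])
  if (is.na(ntax) || is.na(nchar))
    stop("DIMENSIONS must give NTAX and NCHAR")
  fmt <- nexus_keyvals(block, "FORMAT")
  datatype <- toupper(fmt[["DATATYPE"]] %||% "STANDARD")
  mat_txt <- sub(".*?\\bMATRIX\\b", "", block, ignore.case = TRUE)
  mat_txt <- sub(";.*$", "", mat_txt)
  rows <- parse_matrix_rows(mat_txt)
  if (length(rows) != ntax)
    stop("matrix has ", length(rows), " rows but NTAX=", ntax)
  taxa <- vapply(rows, `[[`, character(1), "taxon")
  if (datatype == "CONTINUOUS") {
    vals <- t(vapply(rows, function(r) {
      v <- parse_continuous_cells(r$data)
      if (length(v) != nchar)
        stop("taxon ", r$taxon, " has ", length(v),
             " values but NCHAR=", nchar)
      v
    }, numeric(nchar)))
    continuous_matrix(vals, taxa = taxa)
  } else {
    cells <- lapply(rows, function(r) {
      v <- tokenize_discrete_row(r$data)
      if (length(v) != nchar)
        stop("taxon ", r$taxon, " has ", length(v),
             " characters but NCHAR=", nchar)
      v
    })
    states <- matrix(vector("list", ntax * nchar), ntax, nchar)
    for (i in seq_len(ntax)) for (j in seq_len(nchar))
      states[[i, j]] <- parse_discrete_cell(cells[[i]][j])
    discrete_matrix(states, taxa = taxa)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

strip_nexus_comments <- function(txt) gsub("\\[[^]]*\\]", "", txt)

extract_nexus_block <- function(txt, names) {
  for (nm in names) {
    m <- regexpr(paste0("(?is)BEGIN\\s+", nm, "\\s*;.*?END\\s*;"), txt,
                 perl = TRUE)
    if (m > 0) return(regmatches(txt, m))
  }
  NULL
}

nexus_keyvals <- function(block, command) {
  m <- regexpr(paste0("(?is)\\b", command, "\\b[^;]*;"), block, perl = TRUE)
  if (m < 0) return(list())
  line <- regmatches(block, m)
  pat <- "([A-Za-z]+)\\s*=\\s*(\"[^\"]*\"|'[^']*'|[^\\s;]+)"
  out <- list()
  for (piece in regmatches(line, gregexpr(pat, line, perl = TRUE))[[1]]) {
    kv <- regmatches(piece, regexec(pat, piece, perl = TRUE))[[1]]
    out[[toupper(kv[2])]] <- gsub("^[\"']|[\"']$", "", kv[3])
  }
  out
}

# one row per line: taxon token (possibly quoted) + data remainder
parse_matrix_rows <- function(mat_txt) {
  lines <- trimws(strsplit(mat_txt, "\n")[[1]])
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    if (startsWith(ln, "'")) {
      end <- regexpr("'", substring(ln, 2)) + 1L
      taxon <- substring(ln, 2, end - 1L)
      rest <- trimws(substring(ln, end + 1L))
    } else {
      sp <- regexpr("[[:space:]]", ln)
      if (sp < 0) stop("matrix row with no data: '", ln, "'")
      taxon <- substring(ln, 1, sp - 1L)
      rest <- trimws(substring(ln, sp + 1L))
    }
    taxon <- gsub(" ", "_", taxon)
    list(taxon = taxon, data = rest)
  })
}

# split a discrete row into cell strings, honouring {...} and (...)
tokenize_discrete_row <- function(s) {
  s <- gsub("[[:space:]]", "", s)
  chars <- strsplit(s, "")[[1]]
  out <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch %in% c("{", "(")) {
      close <- if (ch == "{") "}" else ")"
      j <- i
      while (j <= length(chars) && chars[j] != close) j <- j + 1L
      if (j > length(chars)) stop("unclosed polymorphism bracket in row")
      out <- c(out, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else {
      out <- c(out, ch)
      i <- i + 1L
    }
  }
  out
}

parse_continuous_cells <- function(s) {
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1]]
  vals <- suppressWarnings(as.numeric(toks))
  vals[toks %in% c("?", "-")] <- NA_real_
  bad <- is.na(vals) & !toks %in% c("?", "-")
  if (any(bad)) stop("unreadable continuous cell: '", toks[bad][1], "'")
  vals
}

#' Write a character matrix to NEXUS
#'
#' @param m a `discrete_matrix` or `continuous_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(m, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#NEXUS", con)
  if (inherits(m, "discrete_matrix")) {
    maxst <- max(c(0L, unlist(m$states)), na.rm = TRUE)
    symbols <- paste(state_symbol(0:maxst), collapse = "")
    writeLines(c("BEGIN CHARACTERS;",
                 sprintf("\tDIMENSIONS NTAX=%d NCHAR=%d;",
                         length(m$taxa), m$nchar),
                 sprintf(
                   "\tFORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
                   symbols),
                 "\tMATRIX"), con)
    for (i in seq_along(m$taxa)) {
      row <- vapply(seq_len(m$nchar), function(j)
        format_discrete_cell(m$states[[i, j]]), character(1))
      writeLines(paste0("\t", m$taxa[i], "\t", paste(row, collapse = "")), con)
    }
  } else if (inherits(m, "continuous_matrix")) {
    writeLines(c("BEGIN CHARACTERS;",
                 sprintf("\tDIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
                 "\tFORMAT DATATYPE=CONTINUOUS MISSING=?;",
                 "\tMATRIX"), con)
    for (i in seq_len(nrow(m))) {
      vals <- ifelse(is.na(m[i, ]), "?", format(m[i, ], digits = 15))
      writeLines(paste0("\t", rownames(m)[i], "\t",
                        paste(vals, collapse = " ")), con)
    }
  } else stop("unsupported matrix type")
  writeLines(c("\t;", "END;"), con)
  invisible(path)
}

state_symbol <- function(s) ifelse(s < 10, as.character(s), LETTERS[s - 9L])

format_discrete_cell <- function(st) {
  if (cell_is_missing(st)) return("?")
  if (length(st) == 1L) return(state_symbol(st))
  paste0("{", paste(state_symbol(st), collapse = ""), "}")
}

#' Read a TNT xread matrix
#'
#' Supports the `xread` format with optional `&[continuous]` and
#' `&[num]` blocks; continuous characters are returned separately from
#' discrete ones. A file with no block markers is read as discrete only.
#'
#' @param path path to a TNT file.
#' @return list with elements `discrete` (a `discrete_matrix`, possibly with
#'   zero characters) and `continuous` (a `continuous_matrix`, possibly with
#'   zero characters).
#' @export
read_tnt <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("'[^']*'", "", txt)                     # quoted title
  m <- regexpr("(?is)\\bxread\\b(.*?);", txt, perl = TRUE)
  if (m < 0) stop("no xread block in ", path)
  body <- sub("(?is)\\bxread\\b", "", regmatches(txt, m), perl = TRUE)
  body <- sub(";\\s*$", "", body)
  # leading dimensions: nchar ntax
  dm <- regexec("^\\s*(\\d+)\\s+(\\d+)", body)[[1]]
  if (dm[1] < 0) stop("xread must begin with 'nchar ntax'")
  nchar_total <- as.integer(regmatches(body, regexec(
    "^\\s*(\\d+)\\s+(\\d+)", body))[[1]][2])
  ntax <- as.integer(regmatches(body, regexec(
    "^\\s*(\\d+)\\s+(\\d+)", body))[[1]][3])
  body <- sub("^\\s*\\d+\\s+\\d+", "", body)
  # split into &[type] blocks
  starts <- gregexpr("&\\[[A-Za-z]+\\]", body)[[1]]
  blocks <- list()
  if (starts[1] < 0) {
    blocks <- list(list(type = "num", text = body))
  } else {
    labs <- regmatches(body, gregexpr("&\\[[A-Za-z]+\\]", body))[[1]]
    bounds <- c(starts, nchar(body) + 1L)
    for (k in seq_along(labs)) {
      type <- tolower(gsub("[][&]", "", labs[k]))
      seg <- substring(body, bounds[k] + nchar(labs[k]), bounds[k + 1L] - 1L)
      blocks[[length(blocks) + 1L]] <- list(type = type, text = seg)
    }
  }
  disc <- list(); cont <- list(); taxa <- NULL
  for (b in blocks) {
    rows <- parse_matrix_rows(b$text)
    tx <- vapply(rows, `[[`, character(1), "taxon")
    if (is.null(taxa)) taxa <- tx
    else if (!setequal(taxa, tx))
      stop("taxon sets differ between xread blocks")
    ord <- match(taxa, tx)
    if (b$type %in% c("continuous", "cont")) {
      vals <- lapply(rows[ord], function(r) parse_continuous_cells(r$data))
      n <- unique(lengths(vals))
      if (length(n) != 1L) stop("ragged continuous block")
      cont[[length(cont) + 1L]] <- do.call(rbind, vals)
    } else {
      cells <- lapply(rows[ord], function(r) tokenize_discrete_row(r$data))
      n <- unique(lengths(cells))
      if (length(n) != 1L) stop("ragged discrete block")
      disc[[length(disc) + 1L]] <- cells
    }
  }
  ncont <- sum(vapply(cont, ncol, integer(1)))
  ndisc <- sum(vapply(disc, function(d) length(d[[1]]), integer(1)))
  if (ncont + ndisc != nchar_total)
    stop("xread declares ", nchar_total, " characters but ",
         ncont + ndisc, " were read")
  if (length(taxa) != ntax)
    stop("xread declares ", ntax, " taxa but ", length(taxa), " were read")
  cont_m <- if (ncont > 0) {
    vals <- do.call(cbind, cont); rownames(vals) <- taxa
    continuous_matrix(vals)
  } else continuous_matrix(matrix(numeric(0), length(taxa), 0,
                                  dimnames = list(taxa, NULL)))
  disc_m <- if (ndisc > 0) {
    states <- matrix(vector("list", length(taxa) * ndisc),
                     length(taxa), ndisc)
    for (i in seq_along(taxa)) {
      row <- unlist(lapply(disc, function(d) d[[i]]))
      for (j in seq_len(ndisc)) states[[i, j]] <- parse_discrete_cell(row[j])
    }
    discrete_matrix(states, taxa = taxa)
  } else discrete_matrix(matrix(vector("list", 0), length(taxa), 0),
                         taxa = taxa)
  list(discrete = disc_m, continuous = cont_m)
}

#' Read / write newick trees
#'
#' Thin wrappers around \pkg{ape} that validate input and preserve the
#' `root.time` attribute (age of the root in Ma) used by dated trees.
#'
#' @param path file path.
#' @return `read_newick`: an `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  n_open <- lengths(regmatches(txt, gregexpr("\\(", txt)))
  n_close <- lengths(regmatches(txt, gregexpr("\\)", txt)))
  if (n_open != n_close)
    stop("unbalanced parentheses in newick file: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick file: ", path)
  tree
}

#' @rdname read_newick
#' @param tree an `ape::phylo` object.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a taxon table (name, fad, lad, diet) from CSV
#'
#' @param path CSV file with columns `name`, `fad`, `lad` and optionally
#'   `diet`.
#' @return a [taxon_records()] data frame.
#' @export
read_taxon_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "fad", "lad")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("taxon table missing columns: ", paste(miss, collapse = ", "))
  if (!all(vapply(df[c("fad", "lad")], is.numeric, logical(1))))
    stop("non-numeric ages in taxon table")
  taxon_records(df$name, df$fad, df$lad, df$diet %||% "unknown")
}
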