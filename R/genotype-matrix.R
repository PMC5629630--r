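#' Construct an F2 genotype matrix
#'
#' The basic data container: one row per F2 individual, one column per
#' marker, with integer codes. Codominant markers use `0` (homozygote for
#' the first parent's allele, file code `A`), `1` (homozygote for the second
#' parent's allele, `B`) and `2` (heterozygote, `H`); dominant markers use
#' `0` (recessive phenotype class) and `1` (dominant phenotype class).
#' Missing calls are `NA` (file code `-`).
#'
#' @param calls integer matrix (individuals x markers) of codes as above.
#' @param markers character vector of unique marker names; defaults to the
#'   column names of `calls` or `M1`, `M2`, ...
#' @param marker_type `"codominant"` or `"dominant"`; applies to the whole
#'   matrix.
#' @return An object of class `genotype_matrix`.
#' @seealso [validate_matrix()], [read_raw()], [write_raw()]
#' @export
genotype_matrix <- function(calls, markers = NULL,
                            marker_type = c("codominant", "dominant")) {
  marker_type <- match.arg(marker_type)
  calls <- as.matrix(calls)
  if (!is.numeric(calls) && !all(is.na(calls)))
    stop("'calls' must be a numeric matrix of genotype codes")
  storage.mode(calls) <- "integer"
  if (is.null(markers)) markers <- colnames(calls)
  if (is.null(markers)) markers <- paste0("M", seq_len(ncol(calls)))
  markers <- as.character(markers)
  if (length(markers) != ncol(calls))
    stop("length of 'markers' (", length(markers),
         ") does not match number of columns (", ncol(calls), ")")
  if (anyDuplicated(markers))
    stop("marker names must be unique; duplicated: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  dimnames(calls) <- list(NULL, markers)
  x <- structure(list(calls = calls, markers = markers,
                      marker_type = marker_type),
                 class = "genotype_matrix")
  validate_matrix(x)
}

#' Validate a genotype matrix
#'
#' Checks rectangularity and code legality and computes the per-marker
#' missing rate (stored in the `"missing_rate"` attribute of the returned
#' object). Illegal codes are reported with the individual (row) and marker
#' they occur at.
#'
#' @param x a [genotype_matrix()].
#' @return `x`, unchanged except for the `"missing_rate"` attribute.
#' @export
validate_matrix <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  calls <- x$calls
  if (!is.matrix(calls))
    stop("genotype calls must form a rectangular matrix")
  legal <- if (x$marker_type == "codominant") c(0L, 1L, 2L) else c(0L, 1L)
  bad <- which(!(calls %in% legal) & !is.na(calls))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(calls)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(calls)) + 1L
    stop("illegal ", x$marker_type, " code '", calls[bad[1]],
         "' for individual ", i, ", marker '", x$markers[j], "'")
  }
  attr(x, "missing_rate") <-
    if (nrow(calls) == 0L) stats::setNames(rep(NA_real_, ncol(calls)), x$markers)
    else colMeans(is.na(calls))
  x
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("F2 genotype matrix: %d individuals x %d %s markers\n",
              nrow(x$calls), length(x$markers), x$marker_type))
  mr <- attr(x, "missing_rate")
  if (!is.null(mr) && length(mr))
    cat(sprintf("missing rate: mean %.1f%% (max %.1f%% at %s)\n",
                100 * mean(mr), 100 * max(mr), x$markers[which.max(mr)]))
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  mr <- attr(validate_matrix(object), "missing_rate")
  data.frame(marker = object$markers,
             missing_rate = as.numeric(mr),
             row.names = NULL)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

## file codes <-> integer codes; B folds into the dominant phenotype class
## when a codominant file is read as dominant (the classic B -> H conversion)
.code_to_int <- function(chars, marker_type, as_dominant, where) {
  out <- rep(NA_integer_, length(chars))
  if (marker_type == "codominant" && !as_dominant) {
    out[chars == "A"] <- 0L; out[chars == "B"] <- 1L; out[chars == "H"] <- 2L
  } else {
    out[chars == "A"] <- 0L
    out[chars %in% c("H", "B", "D")] <- 1L
  }
  legal <- c("A", "B", "H", "D", "-")
  bad <- which(!(chars %in% legal))
  if (length(bad))
    stop("unknown genotype code '", chars[bad[1]], "' at ", where,
         ", position ", bad[1])
  out
}

.int_to_code <- function(v, marker_type) {
  map <- if (marker_type == "codominant") c("A", "B", "H") else c("A", "H")
  out <- rep("-", length(v))
  ok <- !is.na(v)
  out[ok] <- map[v[ok] + 1L]
  out
}

#' Read a MAPMAKER/EXP-style .raw genotype file
#'
#' The dialect: a first line `data type f2 intercross`, a count line
#' `<individuals> <markers> <traits>`, then one line per marker starting
#' with `*name` followed by the code string over `A`, `B`, `H`, `-`
#' (whitespace inside the code string is ignored; a marker's codes may
#' continue on following lines until the declared count is reached).
#'
#' @param path file path.
#' @param as_dominant read codominant codes as dominant phenotypes, folding
#'   `B` into the dominant class (`H`); the stored matrix then has
#'   `marker_type = "dominant"`.
#' @return A [genotype_matrix()].
#' @export
read_raw <- function(path, as_dominant = FALSE) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L)
    stop("truncated file: expected a data-type line and a count line")
  if (!grepl("^\\s*data\\s+type", lines[1], ignore.case = TRUE))
    stop("line 1: expected 'data type ...' header, got: ", lines[1])
  counts <- suppressWarnings(as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]]))
  if (length(counts) < 2L || anyNA(counts[1:2]))
    stop("line 2: expected '<individuals> <markers> [traits]', got: ", lines[2])
  n_ind <- counts[1]; n_mark <- counts[2]
  markers <- character(0)
  codes <- list()
  i <- 3L
  while (i <= length(lines) && length(markers) < n_mark) {
    ln <- trimws(lines[i])
    if (!startsWith(ln, "*"))
      stop("line ", i, ": expected a '*marker' line, got: ", lines[i])
    toks <- strsplit(ln, "\\s+")[[1]]
    name <- sub("^\\*", "", toks[1])
    chars <- strsplit(paste(toks[-1], collapse = ""), "")[[1]]
    i <- i + 1L
    while (length(chars) < n_ind && i <= length(lines) &&
           !startsWith(trimws(lines[i]), "*")) {
      chars <- c(chars, strsplit(gsub("\\s", "", lines[i]), "")[[1]])
      i <- i + 1L
    }
    if (length(chars) != n_ind)
      stop("marker '", name, "': declared ", n_ind, " individuals but found ",
           length(chars), " genotype codes")
    markers <- c(markers, name)
    codes[[name]] <- .code_to_int(chars, "codominant", as_dominant,
                                  paste0("marker '", name, "'"))
  }
  if (length(markers) != n_mark)
    stop("header declares ", n_mark, " markers but file contains ",
         length(markers))
  genotype_matrix(do.call(cbind, codes), markers,
                  if (as_dominant) "dominant" else "codominant")
}

#' Write a genotype matrix to the .raw dialect
#'
#' Lossless round-trip counterpart of [read_raw()] (for dominant matrices
#' the dominant phenotype class is written as `H`). Writes are atomic: the
#' file is assembled under a temporary name and renamed into place.
#'
#' @param x a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raw <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (nrow(x$calls) == 0L || ncol(x$calls) == 0L)
    stop("refusing to write an empty genotype matrix")
  lines <- c("data type f2 intercross",
             sprintf("%d %d 0", nrow(x$calls), ncol(x$calls)),
             vapply(seq_along(x$markers), function(j) {
               paste0("*", x$markers[j], " ",
                      paste(.int_to_code(x$calls[, j], x$marker_type),
                            collapse = ""))
             }, character(1)))
  .write_atomic(lines, path)
}

#' Read / write the TSV genotype layout (individuals as rows)
#'
#' A plain alternative to the .raw dialect: a header row of marker names and
#' one row per individual with codes `A`/`B`/`H`/`-`.
#'
#' @inheritParams read_raw
#' @export
read_geno_tsv <- function(path, as_dominant = FALSE) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  markers <- colnames(tab)
  calls <- vapply(seq_along(markers), function(j) {
    .code_to_int(tab[[j]], "codominant", as_dominant,
                 paste0("marker '", markers[j], "'"))
  }, integer(nrow(tab)))
  if (nrow(tab) == 1L) calls <- matrix(calls, nrow = 1L)
  genotype_matrix(calls, markers,
                  if (as_dominant) "dominant" else "codominant")
}

#' @rdname read_geno_tsv
#' @param x a [genotype_matrix()].
#' @export
write_geno_tsv <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (nrow(x$calls) == 0L || ncol(x$calls) == 0L)
    stop("refusing to write an empty genotype matrix")
  body <- apply(x$calls, 1L, function(row)
    paste(.int_to_code(row, x$marker_type), collapse = "\t"))
  .write_atomic(c(paste(x$markers, collapse = "\t"), body), path)
}

.write_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.remove(tmp)
    stop("cannot write to ", path)
  }
  invisible(path)
}

## rows with complete calls at the named markers; errors on unknown names
.triple_calls <- function(x, loci) {
  stopifnot(inherits(x, "genotype_matrix"))
  idx <- match(loci, x$markers)
  if (anyNA(idx))
    stop("marker(s) not found: ", paste(loci[is.na(idx)], collapse = ", "))
  sub <- x$calls[, idx, drop = FALSE]
  sub[stats::complete.cases(sub), , drop = FALSE]
}
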