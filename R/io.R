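# Serialization of joint distributions.  Both formats preserve exactness:
# values are written as terminating decimals where the denominator allows it
# and as "num/den" fractions otherwise, and a metadata block records n,
# scale, multiplier, conditioning and the denominator factorization, so a
# read-back reconstructs the exact rational weights bit for bit.

.fmt_int <- function(x) sprintf("%.0f", x)

.meta_lines <- function(pmf) {
  out <- c(
    "# CrossingRuns joint distribution v1",
    paste0("# n=", pmf@n),
    paste0("# scale=", pmf@scale),
    paste0("# m=", pmf@m),
    paste0("# conditioning=", pmf@conditioning),
    paste0("# denFactors=", paste(.fmt_int(pmf@denFactors), collapse = ",")))
  if (!is.null(pmf@params$pNum)) {
    out <- c(out,
             paste0("# pNum=", paste(.fmt_int(pmf@params$pNum), collapse = ",")),
             paste0("# pDen=", paste(.fmt_int(pmf@params$pDen), collapse = ",")))
  }
  out
}

.parse_meta <- function(lines) {
  meta <- list()
  for (ln in grep("^# [A-Za-z]+=", lines, value = TRUE)) {
    kv <- sub("^# ", "", ln)
    key <- sub("=.*$", "", kv)
    val <- sub("^[^=]*=", "", kv)
    meta[[key]] <- val
  }
  meta
}

.num_vec <- function(s) if (is.null(s) || !nzchar(s)) numeric(0) else
  as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]])

# reconstruct the numerator (over den) of one cell from its value string on
# the stated scale; divFactors = c(decimal 10s, times m's) must divide exactly
.parse_cell <- function(s, denB, extraFactors) {
  if (grepl("/", s, fixed = TRUE)) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1L]]
    t <- bi_from_string(parts[1L])
    divF <- extraFactors  # denominator written is den itself
  } else {
    parts <- strsplit(s, ".", fixed = TRUE)[[1L]]
    dec <- if (length(parts) > 1L) parts[2L] else ""
    digits <- paste0(parts[1L], dec)
    t <- bi_mul(bi_from_string(digits), denB)
    divF <- c(rep(10, nchar(dec)), extraFactors)
  }
  qr <- bi_divmod_factored(t, divF)
  if (!bi_is_zero(qr$r)) stop("value string does not divide exactly: ", s)
  qr$q
}

.cells_to_array <- function(cells, n) {
  K <- max(1L, max(vapply(cells, length, integer(1L))))
  arr <- array(0, c(n, n, K))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      v <- cells[[(j - 1L) * n + i]]
      if (!bi_is_zero(v)) arr[i, j, seq_along(v)] <- v
    }
  }
  arr
}

.rebuild_joint <- function(meta, valueMatrix) {
  n <- as.integer(meta$n)
  m <- as.integer(meta$m)
  denF <- .num_vec(meta$denFactors)
  denB <- bi_prod(denF)
  extraF <- if (meta$scale == "times") rep(m, n - 1L) else numeric(0)
  cells <- vector("list", n * n)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      cells[[(j - 1L) * n + i]] <- .parse_cell(valueMatrix[i, j], denB, extraF)
    }
  }
  params <- list()
  if (!is.null(meta$pNum)) {
    params <- list(pNum = .num_vec(meta$pNum), pDen = .num_vec(meta$pDen))
  }
  .new_joint(n, .cells_to_array(cells, n), denF, meta$scale, m,
             meta$conditioning, params)
}

#' Write a joint distribution as CSV
#'
#' Writes the exact weights in the published table layout (rows c = 0..n-1,
#' columns l = 1..n), preceded by a `#`-commented metadata block.  Values are
#' exact: terminating decimals where possible, `"num/den"` fractions
#' otherwise, so [readJointCSV()] reconstructs the object exactly.
#'
#' @param pmf a [JointPMF-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeJointCSV <- function(pmf, path) {
  stopifnot(validObject(pmf))
  vals <- jointWeightStrings(pmf)
  header <- paste(c("c", paste0("l=", 1:pmf@n)), collapse = ",")
  rows <- vapply(seq_len(pmf@n), function(i) {
    paste(c(paste0("c=", i - 1L), vals[i, ]), collapse = ",")
  }, character(1L))
  writeLines(c(.meta_lines(pmf), header, rows), path)
  invisible(path)
}

#' Read a joint distribution from CSV
#'
#' @param path a file written by [writeJointCSV()]
#' @return a [JointPMF-class], exactly equal to the one written
#' @export
readJointCSV <- function(path) {
  lines <- readLines(path)
  meta <- .parse_meta(lines)
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.csv(text = body, header = TRUE, check.names = FALSE,
                         colClasses = "character")
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  .rebuild_joint(meta, vals)
}

#' Write a joint distribution as JSON
#'
#' Serializes the distribution with all exact values as decimal strings (or
#' fractions), the denominator factorization, and the generating
#' probabilities, so that [readJointJSON()] is an exact inverse.
#'
#' @param pmf a [JointPMF-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeJointJSON <- function(pmf, path) {
  stopifnot(validObject(pmf))
  obj <- list(
    format = "CrossingRuns joint distribution v1",
    n = pmf@n, scale = pmf@scale, m = pmf@m, conditioning = pmf@conditioning,
    denFactors = .fmt_int(pmf@denFactors),
    den = bi_to_string(pmf@den),
    weights = unname(apply(jointWeightStrings(pmf), 1L, as.vector,
                           simplify = FALSE)))
  if (!is.null(pmf@params$pNum)) {
    obj$pNum <- .fmt_int(pmf@params$pNum)
    obj$pDen <- .fmt_int(pmf@params$pDen)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a joint distribution from JSON
#'
#' @param path a file written by [writeJointJSON()]
#' @return a [JointPMF-class], exactly equal to the one written
#' @export
readJointJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- as.integer(obj$n)
  vals <- if (is.matrix(obj$weights)) obj$weights
          else matrix(unlist(obj$weights), n, n, byrow = TRUE)
  meta <- list(n = obj$n, scale = obj$scale, m = obj$m,
               conditioning = obj$conditioning,
               denFactors = paste(obj$denFactors, collapse = ","),
               pNum = if (!is.null(obj$pNum)) paste(obj$pNum, collapse = ","),
               pDen = if (!is.null(obj$pDen)) paste(obj$pDen, collapse = ","))
  pmf <- .rebuild_joint(meta, vals)
  if (!bi_eq(pmf@den, bi_from_string(obj$den)))
    stop("denominator mismatch in JSON file")
  pmf
}
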