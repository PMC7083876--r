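#' Read and write genotype files
#'
#' GENEPOP files use 3-digit allele codes per gene copy (so six digits per
#' diploid genotype), `Pop` lines separating population blocks, and a comma
#' after each individual identifier; `000` encodes a missing copy. The CSV
#' dialect is tidy: one row per individual and locus with columns
#' `individual, population, locus, allele1, allele2` (empty = missing).
#' `write_structure()` emits the classic two-rows-per-individual text layout
#' (missing copies as -9) for interoperability with clustering software.
#'
#' @param path File path.
#' @param d A [genotype_data] object.
#' @param title Title line for the GENEPOP header.
#' @return Readers return a [genotype_data] object; writers return `path`
#'   invisibly.
#' @examples
#' d <- genotype_data(array(c(10L, 10L, 11L, 12L), dim = c(1, 2, 2)), "p1")
#' f <- tempfile(fileext = ".gen")
#' write_genepop(d, f)
#' read_genepop(f)
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3) stop("not a GENEPOP file: too short")
  body <- lines[-1]
  pop_idx <- grep("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (length(pop_idx) == 0) stop("not a GENEPOP file: no Pop line")
  # locus names: everything before the first Pop, possibly comma-separated
  loci <- unlist(strsplit(body[seq_len(pop_idx[1] - 1)], ","))
  loci <- trimws(loci)
  loci <- loci[nzchar(loci)]
  L <- length(loci)
  rows <- list(); pops <- character(); ids <- character()
  blocks <- c(pop_idx, length(body) + 1)
  for (b in seq_len(length(pop_idx))) {
    seg <- body[seq(blocks[b] + 1, blocks[b + 1] - 1)]
    for (ln in seg) {
      parts <- strsplit(ln, ",")[[1]]
      if (length(parts) < 2) stop("malformed GENEPOP individual line: ", ln)
      id <- trimws(parts[1])
      genos <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
      if (length(genos) != L) {
        stop("individual ", id, " has ", length(genos), " genotypes, expected ", L)
      }
      a1 <- as.integer(substr(genos, 1, 3))
      a2 <- as.integer(substr(genos, 4, 6))
      a1[a1 == 0] <- NA_integer_
      a2[a2 == 0] <- NA_integer_
      rows[[length(rows) + 1]] <- c(a1, a2)
      pops <- c(pops, paste0("pop", b))
      ids <- c(ids, id)
    }
  }
  n <- length(rows)
  arr <- array(NA_integer_, dim = c(n, L, 2))
  for (i in seq_len(n)) {
    arr[i, , 1] <- rows[[i]][seq_len(L)]
    arr[i, , 2] <- rows[[i]][L + seq_len(L)]
  }
  genotype_data(arr, pops, loci = loci)
}

#' @rdname read_genepop
#' @export
write_genepop <- function(d, path, title = "msatABC export") {
  if (any(d$alleles > 999, na.rm = TRUE)) {
    stop("allele sizes exceed the 3-digit GENEPOP code range")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(d$loci, con)
  code <- function(a) ifelse(is.na(a), "000", sprintf("%03d", a))
  n <- n_individuals(d)
  for (p in levels(d$pop)) {
    writeLines("Pop", con)
    for (i in which(d$pop == p)) {
      g <- paste0(code(d$alleles[i, , 1]), code(d$alleles[i, , 2]))
      writeLines(sprintf("%s_%d ,  %s", p, i, paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' @rdname read_genepop
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("individual", "population", "locus", "allele1", "allele2")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns: ", paste(need, collapse = ", "))
  }
  inds <- unique(df$individual)
  loci <- unique(df$locus)
  arr <- array(NA_integer_, dim = c(length(inds), length(loci), 2))
  i <- match(df$individual, inds)
  l <- match(df$locus, loci)
  arr[cbind(i, l, 1L)] <- suppressWarnings(as.integer(df$allele1))
  arr[cbind(i, l, 2L)] <- suppressWarnings(as.integer(df$allele2))
  pops <- df$population[match(inds, df$individual)]
  genotype_data(arr, pops, loci = loci)
}

#' @rdname read_genepop
#' @param seed Optional seed recorded in the file header comment.
#' @export
write_genotype_csv <- function(d, path, seed = NULL) {
  n <- n_individuals(d)
  L <- n_loci(d)
  df <- data.frame(
    individual = rep(paste0("ind", seq_len(n)), each = L),
    population = rep(as.character(d$pop), each = L),
    locus = rep(d$loci, times = n),
    allele1 = as.vector(t(d$alleles[, , 1])),
    allele2 = as.vector(t(d$alleles[, , 2]))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(report_header(seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname read_genepop
#' @export
write_structure <- function(d, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(d$loci, collapse = "\t"), con)
  popnum <- as.integer(d$pop)
  for (i in seq_len(n_individuals(d))) {
    for (cpy in 1:2) {
      a <- d$alleles[i, , cpy]
      a[is.na(a)] <- -9L
      writeLines(paste(c(paste0("ind", i), popnum[i], a), collapse = "\t"), con)
    }
  }
  invisible(path)
}

# Header comment stamped on CSV reports: package version + seed.
report_header <- function(seed = NULL) {
  ver <- as.character(utils::packageVersion("msatABC"))
  s <- if (is.null(seed)) "unset" else format(seed)
  sprintf("# msatABC %s; seed: %s", ver, s)
}
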