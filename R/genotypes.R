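#' Diploid microsatellite genotype table
#'
#' The central container of the package: allele-size calls (in base pairs) for
#' a set of individuals at a set of loci, together with per-individual
#' metadata. A call is an unordered pair of positive integer fragment sizes or
#' missing as a whole (no half-missing calls: a locus that failed to amplify
#' for an individual is missing for both gene copies).
#'
#' Internally the two gene copies are stored as two `n x L` integer matrices
#' with the smaller size first, so that `{a, b}` and `{b, a}` are the same
#' call. A hidden truth channel (`truth`) can carry the simulated origin of
#' each individual; it is preserved by subsetting but never written to any
#' standard-format export.
#'
#' @param individuals character vector of unique sample IDs.
#' @param a1,a2 integer matrices (`n x L`) of allele sizes; `NA` for missing.
#'   Rows follow `individuals`, columns follow `loci`.
#' @param loci character vector of unique locus names.
#' @param metadata data frame with one row per individual: columns `id`,
#'   `species` (field label, `"A"`/`"B"`), `region` (one of N, W, SW, S) and
#'   `year`. Missing columns are filled with `NA`.
#' @param truth optional data frame (one row per individual) with the hidden
#'   simulation truth, e.g. `true_species` and `hybrid_class`.
#' @return an object of class `msat_table`.
#' @export
msat_table <- function(individuals, a1, a2, loci, metadata = NULL, truth = NULL) {
  individuals <- as.character(individuals)
  loci <- as.character(loci)
  if (anyDuplicated(individuals)) stop("duplicate individual IDs")
  if (anyDuplicated(loci)) stop("duplicate locus names")
  a1 <- matrix(as.integer(a1), nrow = length(individuals), ncol = length(loci))
  a2 <- matrix(as.integer(a2), nrow = length(individuals), ncol = length(loci))
  bad <- xor(is.na(a1), is.na(a2))
  if (any(bad)) stop("half-missing calls are not allowed")
  if (any(a1 <= 0, na.rm = TRUE) || any(a2 <= 0, na.rm = TRUE))
    stop("allele sizes must be positive integers")
  ## canonical order: smaller size first, so calls are unordered pairs
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(individuals, loci)
  if (is.null(metadata)) {
    n0 <- length(individuals)
    metadata <- data.frame(id = individuals,
                           species = rep(NA_character_, n0),
                           region = rep(NA_character_, n0),
                           year = rep(NA_integer_, n0),
                           stringsAsFactors = FALSE)
  } else {
    metadata <- as.data.frame(metadata)
    if (!"id" %in% names(metadata)) metadata$id <- individuals
    if (!all(metadata$id == individuals)) {
      m <- match(individuals, metadata$id)
      if (anyNA(m)) stop("metadata does not cover all individuals")
      metadata <- metadata[m, , drop = FALSE]
    }
    for (col in c("species", "region", "year"))
      if (!col %in% names(metadata)) metadata[[col]] <- NA
    rownames(metadata) <- NULL
  }
  if (!is.null(truth)) {
    truth <- as.data.frame(truth)
    stopifnot(nrow(truth) == length(individuals))
    rownames(truth) <- NULL
  }
  structure(list(individuals = individuals, loci = loci, a1 = a1, a2 = a2,
                 metadata = metadata, truth = truth),
            class = "msat_table")
}

#' @export
print.msat_table <- function(x, ...) {
  miss <- mean(is.na(x$a1))
  cat(sprintf("<msat_table> %d individuals x %d loci (%.1f%% missing calls)\n",
              length(x$individuals), length(x$loci), 100 * miss))
  sp <- table(x$metadata$species, useNA = "ifany")
  cat("  field species labels:", paste(names(sp), sp, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.msat_table <- function(x) c(length(x$individuals), length(x$loci))

#' Subset a genotype table by loci
#'
#' Used to form the reduced locus panels of the analysis: dropping loci with
#' high null-allele frequencies (9 -> 8 loci) or the species-diagnostic /
#' outlier loci (9 -> 6 loci).
#'
#' @param table an [msat_table()].
#' @param keep character vector of locus names to retain, or `NULL`.
#' @param drop character vector of locus names to remove, or `NULL`. Exactly
#'   one of `keep`/`drop` may be given; both `NULL` returns the table intact.
#' @return an `msat_table` over the requested loci; individuals, metadata and
#'   the truth channel are untouched.
#' @export
subset_loci <- function(table, keep = NULL, drop = NULL) {
  stopifnot(inherits(table, "msat_table"))
  if (!is.null(keep) && !is.null(drop)) stop("give either 'keep' or 'drop', not both")
  if (is.null(keep) && is.null(drop)) return(table)
  want <- if (is.null(keep)) setdiff(table$loci, drop) else keep
  unknown <- setdiff(c(keep, drop), table$loci)
  if (length(unknown)) stop("unknown locus name(s): ", paste(unknown, collapse = ", "))
  idx <- match(want, table$loci)
  msat_table(table$individuals, table$a1[, idx, drop = FALSE],
             table$a2[, idx, drop = FALSE], table$loci[idx],
             metadata = table$metadata, truth = table$truth)
}

#' Subset a genotype table by individuals
#'
#' @param table an [msat_table()].
#' @param ids character vector of individual IDs, or a logical/integer index.
#' @return an `msat_table` restricted to those individuals, metadata and truth
#'   rows kept in alignment.
#' @export
subset_individuals <- function(table, ids) {
  stopifnot(inherits(table, "msat_table"))
  idx <- if (is.character(ids)) match(ids, table$individuals) else seq_along(table$individuals)[ids]
  if (anyNA(idx)) stop("unknown individual ID(s)")
  msat_table(table$individuals[idx], table$a1[idx, , drop = FALSE],
             table$a2[idx, , drop = FALSE], table$loci,
             metadata = table$metadata[idx, , drop = FALSE],
             truth = if (is.null(table$truth)) NULL else table$truth[idx, , drop = FALSE])
}

#' Combine two genotype tables over the same locus panel
#'
#' @param x,y `msat_table`s with identical loci.
#' @return row-bound `msat_table`.
#' @export
rbind_tables <- function(x, y) {
  stopifnot(identical(x$loci, y$loci))
  tr <- NULL
  if (!is.null(x$truth) || !is.null(y$truth)) {
    blank <- function(t, n) if (is.null(t)) data.frame(row.names = seq_len(n)) else t
    tx <- blank(x$truth, length(x$individuals)); ty <- blank(y$truth, length(y$individuals))
    cols <- union(names(tx), names(ty))
    for (col in cols) {
      if (!col %in% names(tx)) tx[[col]] <- NA
      if (!col %in% names(ty)) ty[[col]] <- NA
    }
    tr <- rbind(tx[cols], ty[cols])
  }
  msat_table(c(x$individuals, y$individuals), rbind(x$a1, y$a1), rbind(x$a2, y$a2),
             x$loci, metadata = rbind(x$metadata, y$metadata), truth = tr)
}

#' Per-locus allele frequency spectra
#'
#' Tabulates observed allele frequencies per locus within groups of
#' individuals (missing calls dropped locus-wise).
#'
#' @param table an [msat_table()].
#' @param group factor/character of length `n` assigning individuals to
#'   populations; defaults to the field species label.
#' @return nested list `[[locus]][[population]]`, each element a list with
#'   `locus`, `population`, `freq` (named numeric summing to 1; names are
#'   allele sizes) and `n_gene_copies`.
#' @export
allele_freqs <- function(table, group = table$metadata$species) {
  group <- as.character(group)
  out <- list()
  for (l in seq_along(table$loci)) {
    locus <- table$loci[l]
    out[[locus]] <- list()
    for (g in unique(group[!is.na(group)])) {
      rows <- which(group == g & !is.na(table$a1[, l]))
      sizes <- c(table$a1[rows, l], table$a2[rows, l])
      tab <- table(sizes)
      freq <- as.numeric(tab) / sum(tab)
      names(freq) <- names(tab)
      out[[locus]][[g]] <- list(locus = locus, population = g, freq = freq,
                                n_gene_copies = sum(tab))
    }
  }
  out
}

## ---- GenePop dialect -------------------------------------------------------

#' Read a GenePop file into a genotype table
#'
#' Understands the common dialect: a title line, locus names (one per line or
#' comma-separated on one line), `POP` separators, and per-individual rows
#' `id , 094100 110110 ...` with 2- or 3-digit per-allele coding. The
#' all-zeros code is a missing call. Allele codes are decoded to integer
#' fragment sizes directly (an optional `offset` is added, for panels whose
#' sizes exceed the 3-digit code space).
#'
#' @param path file path, or a character vector of lines via `text`.
#' @param text optional character scalar/vector with the file content.
#' @param pop_labels species labels assigned to the populations in file order
#'   (recycled to the number of POP blocks); default `"A"`, `"B"`, ...
#' @param offset integer added to every decoded allele size (default 0).
#' @return an [msat_table()].
#' @export
read_genepop <- function(path = NULL, text = NULL, pop_labels = NULL, offset = 0L) {
  lines <- if (!is.null(text)) unlist(strsplit(paste(text, collapse = "\n"), "\n"))
           else readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  lines <- lines[nzchar(lines) | seq_along(lines) == 1]
  if (length(lines) < 3) stop("not a GenePop file: too few lines")
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("no POP separator found")
  header <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(paste(header, collapse = ","), ",")))
  loci <- loci[nzchar(loci)]
  L <- length(loci)

  ids <- character(0); pop_of <- integer(0)
  g1 <- list(); g2 <- list()
  pop_idx <- 0L
  for (i in seq(first_pop, length(lines))) {
    ln <- lines[i]
    if (toupper(trimws(ln)) == "POP") { pop_idx <- pop_idx + 1L; next }
    parts <- strsplit(ln, ",")[[1]]
    if (length(parts) < 2)
      stop(sprintf("GenePop parse error at line %d: no 'id ,' separator", i))
    id <- trimws(parts[1])
    codes <- strsplit(trimws(paste(parts[-1], collapse = ",")), "\\s+")[[1]]
    if (length(codes) != L)
      stop(sprintf("GenePop parse error at line %d: %d genotypes for %d loci",
                   i, length(codes), L))
    nc <- nchar(codes)
    if (any(nc %% 2 != 0 | !(nc %in% c(4L, 6L))))
      stop(sprintf("GenePop format error at line %d: allele codes must be 4 or 6 digits", i))
    w <- nc / 2
    c1 <- as.integer(substr(codes, 1, w))
    c2 <- as.integer(substr(codes, w + 1, nc))
    miss <- c1 == 0L & c2 == 0L
    if (any((c1 == 0L) != (c2 == 0L)))
      stop(sprintf("GenePop format error at line %d: half-missing genotype", i))
    c1[miss] <- NA_integer_; c2[miss] <- NA_integer_
    ids <- c(ids, id); pop_of <- c(pop_of, pop_idx)
    g1[[length(g1) + 1L]] <- c1 + ifelse(is.na(c1), 0L, as.integer(offset))
    g2[[length(g2) + 1L]] <- c2 + ifelse(is.na(c2), 0L, as.integer(offset))
  }
  a1 <- do.call(rbind, g1); a2 <- do.call(rbind, g2)
  if (is.null(pop_labels)) pop_labels <- LETTERS[seq_len(max(pop_of))]
  species <- rep_len(pop_labels, max(pop_of))[pop_of]
  msat_table(ids, a1, a2, loci,
             metadata = data.frame(id = ids, species = species,
                                   region = NA_character_, year = NA_integer_,
                                   stringsAsFactors = FALSE))
}

#' Write a genotype table as GenePop text
#'
#' Emits the canonical 3-digit dialect, one POP block per species label (in
#' first-appearance order), missing calls encoded as `000000`. Sizes above
#' 999 are written modulo an `offset` that the caller must supply (and record
#' in a sidecar) — sizes in this package's simulations stay below 1000.
#'
#' @param table an [msat_table()].
#' @param path optional output file; when `NULL` the lines are returned.
#' @param title first line of the file.
#' @param offset integer subtracted from every size before encoding.
#' @return invisibly, the character vector of lines.
#' @export
write_genepop <- function(table, path = NULL, title = "hakecheck export", offset = 0L) {
  sizes <- c(table$a1, table$a2) - offset
  if (any(sizes < 1 | sizes > 999, na.rm = TRUE))
    stop("allele sizes outside 1..999 after offset; supply a suitable offset")
  enc <- function(m) {
    x <- sprintf("%03d", m - as.integer(offset))
    x[is.na(m)] <- "000"
    matrix(x, nrow = nrow(m))
  }
  e1 <- enc(table$a1); e2 <- enc(table$a2)
  lines <- c(title, table$loci)
  species <- table$metadata$species
  species[is.na(species)] <- "NA"
  for (sp in unique(species)) {
    lines <- c(lines, "POP")
    rows <- which(species == sp)
    body <- vapply(rows, function(r)
      paste0(table$individuals[r], " , ",
             paste0(e1[r, ], e2[r, ], collapse = " ")), character(1))
    lines <- c(lines, body)
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read / write the metadata sidecar
#'
#' Tab-delimited with columns `id`, `species`, `region`, `year`. The region
#' vocabulary is fixed to N, W, SW, S.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "region", "year")
  if (!all(need %in% names(md))) stop("metadata must have columns id, species, region, year")
  bad <- !is.na(md$region) & !md$region %in% c("N", "W", "SW", "S")
  if (any(bad)) stop("region must be one of N, W, SW, S")
  md
}

#' @rdname read_metadata
#' @param metadata data frame as returned by [read_metadata()].
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
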