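#' Read MELT-style genotype calls from a VCF file
#'
#' Parses a MELT output VCF (Split mode, which discovers insertions absent
#' from the reference, or Deletion mode, which genotypes reference
#' insertions) into a long table of per-species genotype calls. Genotype
#' semantics depend on the mode: in Split mode the ALT allele is the
#' insertion, so `1/1` is `hom_present`; in Deletion mode the ALT allele is
#' the deletion of a reference insertion, so `1/1` is `hom_absent`.
#' Heterozygous calls are `het` in both modes.
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @param mode `"split"` or `"deletion"`; determines genotype polarity and
#'   whether the `ASSESS` INFO key is extracted.
#' @return a data frame of calls with columns `species`, `locus_id`,
#'   `chrom`, `pos`, `mode`, `genotype` (one of `hom_absent`, `het`,
#'   `hom_present`, `missing`), `filter_status`, `assess`.
#' @seealso [filter_melt_calls()], [build_matrix()]
#' @export
read_melt_vcf <- function(path, mode = c("split", "deletion")) {
  mode <- match.arg(mode)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  filt <- fix[, "FILTER"]
  alt <- fix[, "ALT"]
  family <- sub("^<(INS|DEL):ME:([^>]+)>$", "\\2", alt)
  family[family == alt | is.na(family)] <- toupper(mode)
  locus_id <- paste(chrom, pos, family, sep = ":")
  assess <- if (mode == "split") {
    suppressWarnings(as.integer(vcfR::extract.info(vcf, element = "ASSESS")))
  } else {
    rep(NA_integer_, length(pos))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no sample genotype columns: ", path)
  species <- colnames(gt)
  out <- do.call(rbind, lapply(seq_along(species), function(s) {
    data.frame(species = species[s], locus_id = locus_id, chrom = chrom,
               pos = pos, mode = mode,
               genotype = decode_gt(gt[, s], mode),
               filter_status = filt, assess = assess,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

decode_gt <- function(gt, mode) {
  gt <- gsub("\\|", "/", gt)
  g <- rep("missing", length(gt))
  g[gt %in% c("0/0")] <- "hom_ref"
  g[gt %in% c("0/1", "1/0")] <- "het"
  g[gt %in% c("1/1")] <- "hom_alt"
  if (mode == "split") {
    g[g == "hom_ref"] <- "hom_absent"
    g[g == "hom_alt"] <- "hom_present"
  } else {
    g[g == "hom_ref"] <- "hom_present"   # reference carries the insertion
    g[g == "hom_alt"] <- "hom_absent"    # homozygous deletion of it
  }
  g
}

#' Quality-filter MELT genotype calls
#'
#' Retains Split-mode calls with `filter_status == "PASS"` and
#' `assess >= min_assess`; Deletion-mode calls are retained on PASS alone
#' (MELT emits the ASSESS score only in insertion-discovery mode). Counts
#' of records dropped, by reason, are attached as attribute `"dropped"`.
#'
#' @param calls a call table as produced by [read_melt_vcf()].
#' @param min_assess minimum ASSESS score for Split-mode calls; the default
#'   2 keeps scores strictly greater than 1.
#' @param on_error `"abort"` (default) or `"skip"` for records missing a
#'   required field.
#' @return the retained calls, original order preserved.
#' @export
filter_melt_calls <- function(calls, min_assess = 2, on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  req <- c("species", "locus_id", "mode", "genotype", "filter_status")
  miss <- setdiff(req, names(calls))
  if (length(miss)) stop("call table lacks required columns: ", paste(miss, collapse = ", "))
  malformed <- !stats::complete.cases(calls[req])
  if (any(malformed)) {
    msg <- sprintf("%d malformed call record(s) (missing required field), e.g. record %d",
                   sum(malformed), which(malformed)[1])
    if (on_error == "abort") stop(msg)
    warning(msg, "; skipped")
  }
  is_split <- calls$mode == "split"
  pass <- calls$filter_status == "PASS"
  assess_ok <- !is_split | (!is.na(calls$assess) & calls$assess >= min_assess)
  keep <- !malformed & pass & assess_ok
  dropped <- c(malformed = sum(malformed),
               non_pass = sum(!malformed & !pass),
               low_assess = sum(!malformed & pass & !assess_ok))
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Build a presence/absence matrix from genotype calls
#'
#' Maps genotypes to binary states: `hom_present` and `het` become `1`
#' (a heterozygous genotype counts as presence of the insertion in that
#' species), `hom_absent` becomes `0`, and `missing` or absent records
#' become `NA`. When the same (species, locus) pair was called in both
#' MELT modes with conflicting genotypes, the Deletion-mode call wins with
#' a warning (it genotypes the reference insertion directly); conflicting
#' duplicates within one mode are an error.
#'
#' @param calls a (filtered) call table.
#' @param taxa ordered taxon labels for the matrix rows; defaults to the
#'   sorted species present in `calls`. Species in `calls` but not in
#'   `taxa` are an error.
#' @return a [pa_matrix()] with one column per locus seen in `calls`.
#' @export
build_matrix <- function(calls, taxa = NULL) {
  if (is.null(taxa)) taxa <- sort(unique(calls$species))
  unknown <- setdiff(unique(calls$species), taxa)
  if (length(unknown)) stop("species not in `taxa`: ", paste(unknown, collapse = ", "))
  calls <- calls[calls$genotype != "missing", , drop = FALSE]
  key <- paste(calls$species, calls$locus_id, sep = "\r")
  if (anyDuplicated(key)) {
    calls <- resolve_duplicates(calls, key)
    key <- paste(calls$species, calls$locus_id, sep = "\r")
  }
  loci <- unique(calls$locus_id)
  m <- matrix(NA_integer_, length(taxa), length(loci),
              dimnames = list(taxa, loci))
  state <- ifelse(calls$genotype %in% c("het", "hom_present"), 1L,
                  ifelse(calls$genotype == "hom_absent", 0L, NA_integer_))
  m[cbind(match(calls$species, taxa), match(calls$locus_id, loci))] <- state
  meta <- NULL
  if (all(c("chrom", "pos") %in% names(calls))) {
    first <- calls[!duplicated(calls$locus_id), c("locus_id", "chrom", "pos")]
    meta <- first[match(loci, first$locus_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  pa_matrix(m, loci_meta = meta)
}

resolve_duplicates <- function(calls, key) {
  dup_keys <- unique(key[duplicated(key)])
  drop <- logical(nrow(calls))
  n_conflict <- 0L
  for (k in dup_keys) {
    idx <- which(key == k)
    g <- unique(calls$genotype[idx])
    if (length(g) == 1L) {         # identical duplicates: keep the first
      drop[idx[-1]] <- TRUE
      next
    }
    modes <- calls$mode[idx]
    if (length(unique(modes)) == 1L) {
      stop("conflicting duplicate calls within mode '", modes[1], "' at locus ",
           calls$locus_id[idx[1]], " for ", calls$species[idx[1]])
    }
    keep <- idx[modes == "deletion"][1]
    drop[setdiff(idx, keep)] <- TRUE
    n_conflict <- n_conflict + 1L
  }
  if (n_conflict > 0)
    warning(n_conflict, " (species, locus) pair(s) had conflicting Split/Deletion ",
            "genotypes; Deletion-mode call retained")
  calls[!drop, , drop = FALSE]
}

#' Keep only completely genotyped loci
#'
#' Retains exactly the columns with no missing state, implementing the
#' no-missing-data requirement for the phylogenomic matrix.
#'
#' @param m a [pa_matrix()].
#' @return a `pa_matrix` with the same taxa; possibly zero columns.
#' @export
filter_complete <- function(m) {
  m[, colSums(is.na(m)) == 0L, drop = FALSE]
}

#' Keep only phylogenetically informative loci
#'
#' A column is retained when at least `min_present` taxa carry the
#' insertion and at least `min_absent` lack it. The defaults (2/2) give
#' the standard binary parsimony-informative set; `min_absent = 1` relaxes
#' to the Dollo-informative set in which an (n-1)-presence pattern can
#' still require a loss on some trees.
#'
#' @param m a complete [pa_matrix()] (no missing states).
#' @param min_present,min_absent minimum counts of present/absent taxa.
#' @return the filtered `pa_matrix`.
#' @export
filter_informative <- function(m, min_present = 2, min_absent = 2) {
  if (min_present + min_absent > nrow(m))
    stop("min_present + min_absent exceeds the number of taxa")
  stopifnot_complete(m)
  np <- colSums(m)
  m[, np >= min_present & (nrow(m) - np) >= min_absent, drop = FALSE]
}

#' Per-species heterozygosity of insertion calls
#'
#' Fraction of heterozygous genotypes among non-missing genotyped calls,
#' per species.
#'
#' @param calls a call table (see [read_melt_vcf()]).
#' @param species optional species label(s) to restrict to.
#' @return named numeric vector of fractions in \[0, 1\]; `NA` (with a
#'   warning) for a species with zero genotyped calls.
#' @export
heterozygosity <- function(calls, species = NULL) {
  if (is.null(species)) species <- sort(unique(calls$species))
  out <- vapply(species, function(s) {
    g <- calls$genotype[calls$species == s & calls$genotype != "missing"]
    if (length(g) == 0L) {
      warning("no genotyped calls for species ", s, "; heterozygosity undefined")
      return(NA_real_)
    }
    mean(g == "het")
  }, numeric(1))
  names(out) <- species
  out
}

#' Read or write a binary insertion matrix
#'
#' Three on-disk dialects are supported and round-trip losslessly:
#' * `nexus01`: a NEXUS DATA block, `datatype=standard symbols="01"
#'   missing=?`.
#' * `phylip01`: relaxed PHYLIP; header `ntax nchar`, then one
#'   whitespace-separated `name 01string` line per taxon.
#' * `tsv`: loci as rows with columns `locus_id`, `chrom`, `pos`, then one
#'   column per taxon.
#'
#' @param path file path.
#' @param dialect one of `"nexus01"`, `"phylip01"`, `"tsv"`; default is
#'   guessed from the file extension (`.nex`/`.nexus`, `.phy`/`.phylip`,
#'   otherwise tsv).
#' @return `read_pa_matrix()` returns a [pa_matrix()];
#'   `write_pa_matrix()` returns `path` invisibly.
#' @export
read_pa_matrix <- function(path, dialect = NULL) {
  dialect <- guess_dialect(path, dialect)
  switch(dialect,
         nexus01 = read_nexus01(path),
         phylip01 = read_phylip01(path),
         tsv = read_tsv01(path))
}

#' @rdname read_pa_matrix
#' @param m a [pa_matrix()] to write.
#' @export
write_pa_matrix <- function(m, path, dialect = NULL) {
  dialect <- guess_dialect(path, dialect)
  switch(dialect,
         nexus01 = write_nexus01(m, path),
         phylip01 = write_phylip01(m, path),
         tsv = write_tsv01(m, path))
  invisible(path)
}

guess_dialect <- function(path, dialect) {
  if (!is.null(dialect)) return(match.arg(dialect, c("nexus01", "phylip01", "tsv")))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("nex", "nexus")) "nexus01"
  else if (ext %in% c("phy", "phylip")) "phylip01"
  else "tsv"
}

chars_to_states <- function(ch, where) {
  bad <- !(ch %in% c("0", "1", "?"))
  if (any(bad))
    stop("invalid state symbol '", ch[which(bad)[1]], "' at ", where,
         ", position ", which(bad)[1])
  out <- rep(NA_integer_, length(ch))
  out[ch == "0"] <- 0L
  out[ch == "1"] <- 1L
  out
}

read_nexus01 <- function(path) {
  x <- ape::read.nexus.data(path)
  m <- do.call(rbind, lapply(names(x), function(tx)
    chars_to_states(toupper(x[[tx]]) , paste0("taxon ", tx))))
  rownames(m) <- names(x)
  # locus ids, if the file carries a CHARSTATELABELS command
  lines <- readLines(path)
  i <- grep("CHARSTATELABELS", lines, ignore.case = TRUE)
  if (length(i) == 1) {
    stmt <- sub(".*CHARSTATELABELS", "", paste(lines[i:length(lines)], collapse = " "),
                ignore.case = TRUE)
    stmt <- sub(";.*", "", stmt)
    labs <- vapply(strsplit(trimws(strsplit(stmt, ",")[[1]]), "\\s+"),
                   function(p) p[length(p)], "")
    if (length(labs) == ncol(m)) colnames(m) <- labs
  }
  pa_matrix(m)
}

write_nexus01 <- function(m, path) {
  states <- ifelse(is.na(m), "?", as.character(m))
  rows <- apply(states, 1, paste, collapse = "")
  width <- max(nchar(rownames(m))) + 2L
  labels <- paste(sprintf("%d %s", seq_len(ncol(m)), colnames(m)), collapse = ", ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
    "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? GAP=- INTERLEAVE=NO;",
    sprintf("  CHARSTATELABELS %s;", labels),
    "  MATRIX",
    sprintf("    %-*s%s", width, rownames(m), rows),
    "  ;",
    "END;"), con)
}

read_phylip01 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- scan(text = lines[1], what = integer(), quiet = TRUE)
  if (length(hdr) != 2) stop("malformed PHYLIP header: ", lines[1])
  ntax <- hdr[1]; nchar_ <- hdr[2]
  body <- lines[-1]
  if (length(body) != ntax)
    stop("PHYLIP header declares ", ntax, " taxa but file has ", length(body), " rows")
  parts <- strsplit(trimws(body), "\\s+")
  taxa <- vapply(parts, `[`, "", 1)
  seqs <- vapply(parts, function(p) paste(p[-1], collapse = ""), "")
  if (any(nchar(seqs) != nchar_))
    stop("PHYLIP header declares ", nchar_, " characters but taxon ",
         taxa[which(nchar(seqs) != nchar_)[1]], " has ",
         nchar(seqs)[which(nchar(seqs) != nchar_)[1]])
  m <- do.call(rbind, lapply(seq_along(taxa), function(i)
    chars_to_states(strsplit(seqs[i], "")[[1]], paste0("taxon ", taxa[i]))))
  rownames(m) <- taxa
  pa_matrix(m)
}

write_phylip01 <- function(m, path) {
  states <- ifelse(is.na(m), "?", as.character(m))
  rows <- apply(states, 1, paste, collapse = "")
  width <- max(nchar(rownames(m))) + 2L
  writeLines(c(sprintf("%d %d", nrow(m), ncol(m)),
               sprintf("%-*s%s", width, rownames(m), rows)),
             path)
}

read_tsv01 <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  fixed <- c("locus_id", "chrom", "pos")
  if (!all(fixed %in% names(df)))
    stop("tsv matrix must have columns locus_id, chrom, pos")
  taxa <- setdiff(names(df), fixed)
  m <- t(vapply(taxa, function(tx)
    chars_to_states(df[[tx]], paste0("column ", tx)), integer(nrow(df))))
  colnames(m) <- df$locus_id
  meta <- data.frame(locus_id = df$locus_id, chrom = df$chrom,
                     pos = suppressWarnings(as.integer(df$pos)),
                     stringsAsFactors = FALSE)
  pa_matrix(m, loci_meta = meta)
}

write_tsv01 <- function(m, path) {
  meta <- attr(m, "loci_meta")
  if (is.null(meta))
    meta <- data.frame(locus_id = colnames(m), chrom = NA_character_,
                       pos = NA_integer_, stringsAsFactors = FALSE)
  states <- ifelse(is.na(m), "?", as.character(m))
  df <- cbind(meta[match(colnames(m), meta$locus_id), , drop = FALSE],
              as.data.frame(t(states), stringsAsFactors = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
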