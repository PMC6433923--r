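#' Read per-site stranded allele counts
#'
#' Reads the canonical pileup-count TSV (columns \code{chrom}, \code{pos},
#' \code{ref}, \code{a_plus}, \code{a_minus}, ..., \code{t_minus}; 1-based
#' coordinates) or, auto-detected, single-sample samtools-mpileup text
#' (chrom, pos, ref, depth, base string, quality string), in which case
#' bases below \code{min_base_quality} (phred+33) are excluded from the
#' counts.
#'
#' @param path input file.
#' @param min_base_quality quality floor applied when parsing mpileup text.
#' @return Pileup-format data frame.
#' @export
read_pileup_counts <- function(path, min_base_quality = 25L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    warning("empty pileup file: ", path, call. = FALSE)
    return(empty_pileup())
  }
  if (grepl("^chrom\t", first)) {
    out <- utils::read.delim(path, stringsAsFactors = FALSE)
    return(validate_pileup(out))
  }
  parse_mpileup(readLines(path), min_base_quality)
}

empty_pileup <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             a_plus = integer(), a_minus = integer(), c_plus = integer(),
             c_minus = integer(), g_plus = integer(), g_minus = integer(),
             t_plus = integer(), t_minus = integer(), stringsAsFactors = FALSE)
}

# Parse single-sample samtools-mpileup text lines into stranded counts.
# Base column grammar: '.'/',' match the reference on +/- strand; ACGTN /
# acgtn are mismatches by strand; '^X' starts a read segment (X = mapping
# quality, not a base); '$' ends one; '+n'/' -n' introduce an n-base indel
# sequence (skipped); '*', '<', '>' occupy a quality slot but are not
# counted. One quality character per counted or placeholder base.
parse_mpileup <- function(lines, min_base_quality) {
  rows <- vector("list", length(lines))
  qfloor <- min_base_quality + 33L
  for (li in seq_along(lines)) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) {
      if (nzchar(trimws(lines[li])))
        warning("line ", li, ": malformed mpileup row skipped", call. = FALSE)
      next
    }
    ref <- toupper(f[3]); bases <- f[5]; quals <- f[6]
    cnt <- stats::setNames(integer(8),
                           c("A+", "A-", "C+", "C-", "G+", "G-", "T+", "T-"))
    bs <- strsplit(bases, "")[[1]]
    qs <- utf8ToInt(quals)
    i <- 1L; qi <- 1L
    ok <- TRUE
    while (i <= length(bs)) {
      ch <- bs[i]
      if (ch == "^") { i <- i + 2L; next }
      if (ch == "$") { i <- i + 1L; next }
      if (ch == "+" || ch == "-") {
        j <- i + 1L
        while (j <= length(bs) && grepl("[0-9]", bs[j])) j <- j + 1L
        nlen <- as.integer(paste(bs[(i + 1L):(j - 1L)], collapse = ""))
        i <- j + nlen
        next
      }
      if (qi > length(qs)) { ok <- FALSE; break }
      q <- qs[qi]; qi <- qi + 1L
      base <- NULL; strand <- NULL
      if (ch == ".") { base <- ref; strand <- "+" }
      else if (ch == ",") { base <- ref; strand <- "-" }
      else if (ch %in% c("A", "C", "G", "T")) { base <- ch; strand <- "+" }
      else if (ch %in% c("a", "c", "g", "t")) { base <- toupper(ch); strand <- "-" }
      # '*', '<', '>', 'N'/'n' consume a quality slot but are not counted
      if (!is.null(base) && q >= qfloor) {
        key <- paste0(base, strand)
        cnt[key] <- cnt[key] + 1L
      }
      i <- i + 1L
    }
    if (!ok) {
      warning("line ", li, ": base/quality strings disagree; row skipped",
              call. = FALSE)
      next
    }
    rows[[li]] <- data.frame(
      chrom = f[1], pos = as.integer(f[2]), ref = ref,
      a_plus = cnt[["A+"]], a_minus = cnt[["A-"]],
      c_plus = cnt[["C+"]], c_minus = cnt[["C-"]],
      g_plus = cnt[["G+"]], g_minus = cnt[["G-"]],
      t_plus = cnt[["T+"]], t_minus = cnt[["T-"]],
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_pileup())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read DNA variant calls from a VCF file
#'
#' Minimal VCF 4.x text reader for uncompressed files: extracts CHROM, POS,
#' REF, ALT, QUAL and, from the first sample column, the genotype
#' (\code{"hom"} for 1/1 or 1|1, \code{"het"} for 0/1-style calls) and depth
#' (FORMAT \code{DP}, falling back to INFO \code{DP}).
#'
#' @param path VCF file path.
#' @return Data frame with \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{qual}, \code{genotype}, \code{depth}.
#' @export
read_vcf_variants <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), qual = numeric(),
                      genotype = character(), depth = integer(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  qual <- suppressWarnings(as.numeric(f[, 6]))
  genotype <- rep(NA_character_, nrow(f))
  depth <- rep(NA_integer_, nrow(f))
  if (ncol(f) >= 10L) {
    fmt <- strsplit(f[, 9], ":", fixed = TRUE)
    smp <- strsplit(f[, 10], ":", fixed = TRUE)
    for (i in seq_len(nrow(f))) {
      gi <- match("GT", fmt[[i]]); di <- match("DP", fmt[[i]])
      if (!is.na(gi) && gi <= length(smp[[i]])) {
        gt <- gsub("|", "/", smp[[i]][gi], fixed = TRUE)
        al <- strsplit(gt, "/", fixed = TRUE)[[1]]
        if (!any(al == ".")) {
          genotype[i] <- if (length(unique(al)) == 1L && al[1] != "0")
            "hom" else if (any(al != "0")) "het" else "ref"
        }
      }
      if (!is.na(di) && di <= length(smp[[i]]))
        depth[i] <- suppressWarnings(as.integer(smp[[i]][di]))
    }
  }
  info_dp <- suppressWarnings(as.integer(sub(".*DP=([0-9]+).*", "\\1",
                                             ifelse(grepl("DP=", f[, 8]),
                                                    f[, 8], NA))))
  depth[is.na(depth)] <- info_dp[is.na(depth)]
  data.frame(chrom = f[, 1], pos = as.integer(f[, 2]), ref = f[, 4],
             alt = f[, 5], qual = qual, genotype = genotype, depth = depth,
             stringsAsFactors = FALSE)
}

#' Read a known-SNP position set from VCF or BED
#'
#' VCF rows contribute their POS directly; BED rows (0-based half-open) are
#' converted to 1-based positions (\code{start+1 .. end}). The format is
#' auto-detected from the header/extension.
#'
#' @param path VCF or BED file.
#' @return Duplicate-free data frame of \code{chrom}, \code{pos}.
#' @export
read_snp_positions <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  is_vcf <- grepl("\\.vcf$", path, ignore.case = TRUE) ||
    any(startsWith(utils::head(lines, 5L), "##fileformat=VCF"))
  if (is_vcf) {
    v <- read_vcf_variants(path)
    out <- unique(v[c("chrom", "pos")])
  } else {
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
    if (!length(lines))
      return(data.frame(chrom = character(), pos = integer(),
                        stringsAsFactors = FALSE))
    f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    start <- as.integer(f[, 2]); end <- as.integer(f[, 3])
    out <- unique(do.call(rbind, lapply(seq_len(nrow(f)), function(i)
      data.frame(chrom = f[i, 1], pos = (start[i] + 1L):end[i],
                 stringsAsFactors = FALSE))))
  }
  rownames(out) <- NULL
  out
}

#' Combine read alignments from two aligners
#'
#' Produces exactly one alignment per read identifier: a read mapped by only
#' one aligner is kept as-is; when both aligners place the read, the
#' higher-scoring record wins, whether the placements agree or not; score
#' ties break deterministically (aligner \code{"a"} first, then lexicographic
#' genomic location). Duplicate (read, location) records within one input
#' are deduplicated keeping the best score, with a warning.
#'
#' @param reads_a,reads_b data frames with columns \code{read_id},
#'   \code{chrom}, \code{pos}, \code{strand}, \code{score}, and optionally
#'   \code{aligner} (filled with \code{"a"} / \code{"b"} when absent).
#' @return Combined data frame, one row per read identifier.
#' @export
combine_aligner_reads <- function(reads_a, reads_b) {
  tag <- function(x, lab) {
    if (!"aligner" %in% names(x)) x$aligner <- lab
    need <- c("read_id", "chrom", "pos", "strand", "score")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop("alignment table lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    key <- paste(x$read_id, x$chrom, x$pos)
    if (anyDuplicated(key)) {
      warning("duplicate (read, location) records deduplicated in aligner ",
              lab, call. = FALSE)
      x <- x[order(-x$score), , drop = FALSE]
      x <- x[!duplicated(paste(x$read_id, x$chrom, x$pos)), , drop = FALSE]
    }
    x
  }
  all <- rbind(tag(reads_a, "a"), tag(reads_b, "b"))
  if (nrow(all) == 0L) return(all)
  ord <- order(all$read_id, -all$score, all$aligner, all$chrom, all$pos)
  all <- all[ord, , drop = FALSE]
  out <- all[!duplicated(all$read_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write result tables to a directory
#'
#' Writes each table of a named list as a header-carrying TSV with stable
#' column order, plus a \code{manifest.tsv} listing every file with its row
#' and column counts. The paired reader is [read_results()]; writing then
#' reading restores the tables.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_results <- function(tables, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv(tables[[nm]], p)
    paths <- c(paths, p)
  }
  manifest <- data.frame(file = paste0(names(tables), ".tsv"),
                         n_rows = vapply(tables, nrow, integer(1)),
                         n_cols = vapply(tables, ncol, integer(1)))
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(paths)
}

#' Read result tables written by [write_results()]
#'
#' @param out_dir directory holding a \code{manifest.tsv}.
#' @return Named list of data frames.
#' @export
read_results <- function(out_dir) {
  manifest <- read_tsv(file.path(out_dir, "manifest.tsv"))
  out <- lapply(manifest$file, function(f) read_tsv(file.path(out_dir, f)))
  names(out) <- sub("\\.tsv$", "", manifest$file)
  out
}

write_vcf_file <- function(variants, path, sample = "SAMPLE") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample, sep = "\t")), con)
  if (nrow(variants)) {
    gt <- ifelse(variants$genotype == "hom", "1/1", "0/1")
    writeLines(paste(variants$chrom, variants$pos, ".", variants$ref,
                     variants$alt, variants$qual, "PASS", ".",
                     "GT:DP", paste0(gt, ":", variants$depth), sep = "\t"),
               con)
  }
  invisible(path)
}

#' Write a simulated cohort to a run directory
#'
#' Lays a [simulate_cohort()] result out as the files the pipeline reads:
#' per-sample pileup TSVs (\code{<individual>.<tissue>.<assay>.pileup.tsv}),
#' per-sample VCFs of DNA variant calls, the known-SNP set as BED, the
#' expression and survival TSVs, the truth labels, and a manifest recording
#' the configuration and seed.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir run directory (created).
#' @return Invisibly, \code{dir}.
#' @export
write_run <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tissue in c("normal", "tumor")) {
    for (id in sim$individuals) {
      write_tsv(sim$rna[[tissue]][[id]],
                file.path(dir, sprintf("%s.%s.rna.pileup.tsv", id, tissue)))
      write_tsv(sim$dna[[tissue]][[id]],
                file.path(dir, sprintf("%s.%s.dna.pileup.tsv", id, tissue)))
      write_vcf_file(sim$variants[[tissue]][[id]],
                     file.path(dir, sprintf("%s.%s.dna.vcf", id, tissue)),
                     sample = paste(id, tissue, sep = "_"))
    }
  }
  snp_bed <- data.frame(chrom = sim$snp_set$chrom,
                        start = sim$snp_set$pos - 1L,
                        end = sim$snp_set$pos)
  utils::write.table(snp_bed, file.path(dir, "snp_set.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv(sim$expression, file.path(dir, "expression.tsv"))
  write_tsv(sim$survival, file.path(dir, "survival.tsv"))
  write_tsv(sim$truth$site_class, file.path(dir, "truth_sites.tsv"))
  cfg <- sim$config
  writeLines(c(sprintf("individuals\t%s", paste(sim$individuals, collapse = ",")),
               vapply(names(cfg), function(k)
                 sprintf("%s\t%s", k, paste(format(cfg[[k]]), collapse = ",")),
                 character(1))),
             file.path(dir, "run_manifest.tsv"))
  invisible(dir)
}

#' Load a run directory back into a cohort bundle
#'
#' Reads the files written by [write_run()] into the in-memory structure
#' [discover_cohort()] consumes (count tables, variant calls, SNP set,
#' expression, survival, truth labels).
#'
#' @param dir run directory.
#' @return A cohort bundle list.
#' @export
read_cohort_run <- function(dir) {
  mpath <- file.path(dir, "run_manifest.tsv")
  if (!file.exists(mpath))
    stop("not a run directory (missing ", mpath, ")", call. = FALSE)
  manifest <- readLines(mpath)
  ind_line <- strsplit(manifest[startsWith(manifest, "individuals")][1],
                       "\t")[[1]][2]
  individuals <- strsplit(ind_line, ",", fixed = TRUE)[[1]]
  grab <- function(assay, tissue, reader)
    stats::setNames(lapply(individuals, function(id)
      reader(file.path(dir, sprintf("%s.%s.%s", id, tissue, assay)))),
      individuals)
  list(individuals = individuals,
       rna = list(normal = grab("rna.pileup.tsv", "normal", read_pileup_counts),
                  tumor = grab("rna.pileup.tsv", "tumor", read_pileup_counts)),
       dna = list(normal = grab("dna.pileup.tsv", "normal", read_pileup_counts),
                  tumor = grab("dna.pileup.tsv", "tumor", read_pileup_counts)),
       variants = list(normal = grab("dna.vcf", "normal", read_vcf_variants),
                       tumor = grab("dna.vcf", "tumor", read_vcf_variants)),
       snp_set = read_snp_positions(file.path(dir, "snp_set.bed")),
       expression = read_tsv(file.path(dir, "expression.tsv")),
       survival = read_tsv(file.path(dir, "survival.tsv")),
       truth = list(site_class = read_tsv(file.path(dir, "truth_sites.tsv"))))
}
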