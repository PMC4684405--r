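# Linkage/PED input, founder extraction and per-locus batch analysis.

#' Read a linkage/PED pedigree file
#'
#' Parses a whitespace-delimited pedigree file with the six standard
#' leading columns (family id, individual id, father id, mother id, sex
#' code, phenotype) followed by one pair of allele codes per marker
#' (`0` = missing). Founders are records whose father and mother ids are
#' both `0`. Malformed lines (fewer than eight fields or an odd number of
#' allele columns) are skipped with a warning naming the line numbers;
#' unknown sex codes are kept but flagged and never contribute to counts.
#'
#' @param path Path to the PED file.
#' @param map Optional path to a MAP file; if supplied, its second column
#'   provides marker names (otherwise markers are named `M1, M2, ...`).
#' @return An object of class `"xhwe_ped"`: list with `info` (data.frame:
#'   `family, id, father, mother, sex, phenotype, founder`), `alleles`
#'   (character matrix, two columns per marker) and `markers`.
#' @export
read_ped <- function(path, map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty pedigree file: ", path)
    return(structure(list(info = data.frame(), alleles = NULL,
                          markers = character()),
                     class = "xhwe_ped"))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(fields)
  n_alleles <- max(len) - 6L
  bad <- which(len < 8L | (len - 6L) %% 2L != 0L | len != max(len))
  if (length(bad)) {
    warning("skipping malformed pedigree line(s): ",
            paste(bad, collapse = ", "))
    fields <- fields[-bad]
  }
  if (length(fields) == 0L) {
    stop("no usable records in ", path)
  }
  m <- do.call(rbind, fields)
  sex <- suppressWarnings(as.integer(m[, 5]))
  sex_ok <- sex %in% c(1L, 2L)
  if (any(!sex_ok)) {
    warning(sum(!sex_ok), " record(s) with unknown sex code excluded ",
            "from genotype counts")
  }
  info <- data.frame(family = m[, 1], id = m[, 2], father = m[, 3],
                     mother = m[, 4], sex = ifelse(sex_ok, sex, NA),
                     phenotype = m[, 6],
                     founder = m[, 3] == "0" & m[, 4] == "0")
  alleles <- m[, -(1:6), drop = FALSE]
  n_mark <- ncol(alleles) %/% 2L
  markers <- paste0("M", seq_len(n_mark))
  if (!is.null(map)) {
    mp <- read.table(map, header = FALSE, colClasses = "character")
    if (nrow(mp) == n_mark && ncol(mp) >= 2) markers <- mp[[2]]
  }
  structure(list(info = info, alleles = alleles, markers = markers),
            class = "xhwe_ped")
}

#' @export
print.xhwe_ped <- function(x, ...) {
  cat(sprintf("Pedigree: %d records (%d founders), %d marker(s)\n",
              nrow(x$info), sum(x$info$founder, na.rm = TRUE),
              length(x$markers)))
  invisible(x)
}

#' Genotype counts from genotyped founders at one marker
#'
#' Only founders (no parents in the pedigree) enter the counts, since they
#' are mutually independent. Males are hemizygous: their X genotype is
#' conventionally written as a homozygous pair, so a male record with two
#' identical allele codes contributes that single allele; a male with two
#' different non-missing codes is a genotyping error and is excluded with
#' a warning. Records with any missing allele (`0`) at the marker are
#' excluded at that marker only. By default M1 is the minor allele among
#' the counted founders (males counted once, females twice), ties broken
#' by the lexicographically smaller allele code.
#'
#' @param ped An `"xhwe_ped"` from [read_ped()].
#' @param marker Marker index or name.
#' @param m1 Optional allele code to use as M1 (overrides the minor-allele
#'   rule; swapping M1/M2 swaps `n1m`/`n0m` and `n2f`/`n0f`).
#' @return A [genotype_counts()] object with attributes `marker`, `m1`,
#'   `m2` and `n_excluded`.
#' @export
counts_from_founders <- function(ped, marker, m1 = NULL) {
  stopifnot(inherits(ped, "xhwe_ped"))
  if (is.character(marker)) marker <- match(marker, ped$markers)
  stopifnot(length(marker) == 1L, !is.na(marker), marker >= 1,
            marker <= length(ped$markers))
  use <- ped$info$founder & !is.na(ped$info$sex)
  a <- ped$alleles[use, c(2L * marker - 1L, 2L * marker), drop = FALSE]
  sex <- ped$info$sex[use]
  miss <- a[, 1] == "0" | a[, 2] == "0"
  het_male <- sex == 1L & !miss & a[, 1] != a[, 2]
  if (any(het_male)) {
    warning(sum(het_male), " male founder(s) with discordant allele ",
            "pairs excluded at marker ", ped$markers[marker])
  }
  keep <- !miss & !het_male
  n_excluded <- sum(use) - sum(keep)
  a <- a[keep, , drop = FALSE]
  sex <- sex[keep]
  # allele dosage: one per male, two per female
  alleles <- c(a[sex == 1L, 1], a[sex == 2L, 1], a[sex == 2L, 2])
  codes <- sort(unique(alleles))
  if (length(codes) > 2L) {
    stop("marker ", ped$markers[marker], " has more than two alleles")
  }
  if (is.null(m1)) {
    if (length(codes) == 0L) {
      m1 <- "?"
    } else if (length(codes) == 1L) {
      m1 <- codes
    } else {
      tab <- table(factor(alleles, levels = codes))
      m1 <- if (tab[1] == tab[2]) codes[1] else codes[which.min(tab)]
    }
  }
  male1 <- sex == 1L & a[, 1] == m1
  fem <- sex == 2L
  dose <- (a[, 1] == m1) + (a[, 2] == m1)
  out <- genotype_counts(sum(male1), sum(sex == 1L) - sum(male1),
                         sum(fem & dose == 2), sum(fem & dose == 1),
                         sum(fem & dose == 0))
  attr(out, "marker") <- ped$markers[marker]
  attr(out, "m1") <- m1
  attr(out, "m2") <- setdiff(codes, m1)[1] %||% NA_character_
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Per-locus batch analysis of a pedigree file
#'
#' Runs the selected tests on the genotyped founders of every marker in a
#' PED file, one locus at a time. Each marker's bootstrap stream is
#' sub-seeded from `seed` and the marker index, so a batch run equals the
#' corresponding independent single-locus runs and is reproducible. Loci
#' where a statistic is undefined (e.g. monomorphic markers) are reported
#' with `NA` in that column rather than dropped. A Bonferroni-adjusted
#' significance threshold `alpha / m` (`m` = number of markers analysed)
#' accompanies the report.
#'
#' @inheritParams xhwe_tests
#' @param path Path to the PED file.
#' @param map Optional MAP file path with marker names.
#' @param alpha Nominal per-test significance level.
#' @param out Optional path; if given, the report is written there as a
#'   tab-delimited text table.
#' @return A data.frame (class `"xhwe_locus_reports"`) with one row per
#'   marker: the counts used, the parameter estimates under `H1` and under
#'   each null (`p0`; `p01`, `rho01`; `pm02`, `pf02`), and `stat_*` /
#'   `p_*` columns per test. Attributes: `alpha`, `bonferroni`,
#'   `n_markers`.
#' @export
analyze_file <- function(path,
                         tests = c("Z1", "Z2", "Z0", "LRT0", "LRT1",
                                   "LRT2", "LRT0b", "LRT2b"),
                         alpha = 0.05, B = 1000, seed = 1L,
                         config = em_config(),
                         dosage_compensation = FALSE, map = NULL,
                         out = NULL) {
  ped <- read_ped(path, map = map)
  m <- length(ped$markers)
  if (m == 0L) stop("no markers in ", path)
  rows <- lapply(seq_len(m), function(j) {
    cts <- counts_from_founders(ped, j)
    fit <- .fit_batch(as.data.frame(cts), config$tolerance,
                      config$max_iter, config$rho_init,
                      male_w = if (dosage_compensation) 2 else 1)
    res <- xhwe_tests(cts, tests = tests, B = B,
                      seed = .derive_seed(seed, j), config = config,
                      dosage_compensation = dosage_compensation)
    row <- data.frame(marker = attr(cts, "marker"), m1 = attr(cts, "m1"),
                      n1m = cts$n1m, n0m = cts$n0m, n2f = cts$n2f,
                      n1f = cts$n1f, n0f = cts$n0f,
                      pm1 = fit$pm1, pf1 = fit$pf1, rho1 = fit$rho1,
                      p0 = fit$p0, p01 = fit$p01, rho01 = fit$rho01,
                      pm02 = fit$pm02, pf02 = fit$pf02)
    for (i in seq_len(nrow(res))) {
      row[[paste0("stat_", res$test[i])]] <- res$statistic[i]
      row[[paste0("p_", res$test[i])]] <- res$p_value[i]
    }
    row
  })
  rep <- do.call(rbind, rows)
  attr(rep, "alpha") <- alpha
  attr(rep, "bonferroni") <- alpha / m
  attr(rep, "n_markers") <- m
  class(rep) <- c("xhwe_locus_reports", "data.frame")
  if (!is.null(out)) {
    con <- file(out, "w")
    writeLines(sprintf(
      "# xhweqc per-locus report: %d markers, alpha = %g, Bonferroni threshold = %g",
      m, alpha, alpha / m), con)
    write.table(rep, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  rep
}

#' @export
print.xhwe_locus_reports <- function(x, ...) {
  cat(sprintf(
    "Per-locus X-linked QC report: %d markers, alpha = %g (Bonferroni threshold %.3g)\n",
    attr(x, "n_markers"), attr(x, "alpha"), attr(x, "bonferroni")))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}
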