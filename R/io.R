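## ------------------------------------------------------------------------
## File input (VCF, counts tables), batch testing over markers, and tidy
## result output.
## ------------------------------------------------------------------------

#' Read per-SNP F1 data from a VCF file
#'
#' Reads biallelic tetraploid records from a VCF. With `GT` fields, offspring
#' dosages are the count of alternative alleles among the four called
#' alleles; with `GL` (log10 likelihoods) or `PL` (phred-scaled) fields, each
#' offspring contributes a genotype-likelihood row (`GL` converted as
#' `10^GL`, `PL` as `10^(-PL/10)`). Multi-allelic and non-tetraploid records
#' are skipped with a warning and counted in the `skipped` attribute.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @param parent_ids Optional character vector of the two parent sample
#'   names; remaining samples are offspring unless `offspring_ids` is given.
#' @param offspring_ids Optional character vector of offspring sample names.
#' @param mode `"auto"` (prefer likelihoods when GL/PL present), `"gt"`, or
#'   `"gl"`.
#' @return List of marker records, each a list with `id`, and either `x`
#'   (genotype counts) plus `ell1`/`ell2` (when parents are given in GT
#'   mode), or `G` (genotype-likelihood matrix) plus `a`/`b` (parent
#'   likelihood vectors, when parents are given). Attribute `skipped` counts
#'   skipped records.
#' @export
read_vcf <- function(path, parent_ids = NULL, offspring_ids = NULL,
                     mode = c("auto", "gt", "gl")) {
  mode <- match.arg(mode)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix[, c("CHROM", "POS", "ID", "ALT"), drop = FALSE],
                       stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  if (!is.null(parent_ids)) {
    if (length(parent_ids) != 2L || !all(parent_ids %in% samples)) {
      stop("parent_ids must name two samples present in the VCF", call. = FALSE)
    }
  }
  if (is.null(offspring_ids)) {
    offspring_ids <- setdiff(samples, parent_ids)
  } else if (!all(offspring_ids %in% samples)) {
    stop("offspring_ids not all present in the VCF", call. = FALSE)
  }

  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  lik_key <- if ("GL" %in% fmt_keys) "GL" else if ("PL" %in% fmt_keys) "PL" else NULL
  use_gl <- switch(mode,
    auto = !is.null(lik_key),
    gl = {
      if (is.null(lik_key)) stop("no GL/PL field in VCF", call. = FALSE)
      TRUE
    },
    gt = FALSE
  )

  gt <- vcfR::extract.gt(v, element = "GT")
  lik <- if (use_gl) vcfR::extract.gt(v, element = lik_key) else NULL

  parse_lik <- function(s) {
    if (is.na(s)) return(NULL)
    vals <- suppressWarnings(as.numeric(strsplit(s, ",")[[1]]))
    if (length(vals) != 5L || any(is.na(vals))) return(NULL)
    if (lik_key == "GL") 10^vals else 10^(-vals / 10)
  }
  gt_dosage <- function(s) {
    if (is.na(s) || s %in% c(".", "./.")) return(NA_integer_)
    alleles <- strsplit(s, "[/|]")[[1]]
    if (length(alleles) != 4L || any(alleles == ".")) return(NA_integer_)
    sum(alleles != "0")
  }

  records <- list()
  skipped <- 0L
  for (i in seq_len(nrow(fix))) {
    id <- if (!is.na(fix$ID[i]) && fix$ID[i] != ".") fix$ID[i] else
      paste0(fix$CHROM[i], "_", fix$POS[i])
    if (grepl(",", fix$ALT[i]) || is.na(fix$ALT[i])) {
      warning("skipping multi-allelic record ", id)
      skipped <- skipped + 1L
      next
    }
    if (use_gl) {
      rows <- lapply(lik[i, offspring_ids], parse_lik)
      ok <- !vapply(rows, is.null, logical(1))
      if (!any(ok)) {
        warning("skipping record with no usable likelihoods: ", id)
        skipped <- skipped + 1L
        next
      }
      rec <- list(id = id, G = do.call(rbind, rows[ok]))
      if (!is.null(parent_ids)) {
        ab <- lapply(lik[i, parent_ids], parse_lik)
        if (!any(vapply(ab, is.null, logical(1)))) {
          rec$a <- ab[[1]]
          rec$b <- ab[[2]]
        }
      }
    } else {
      dos <- vapply(gt[i, offspring_ids], gt_dosage, integer(1))
      ploidy_bad <- vapply(gt[i, offspring_ids], function(s) {
        !is.na(s) && length(strsplit(s, "[/|]")[[1]]) != 4L
      }, logical(1))
      if (any(ploidy_bad)) {
        warning("skipping non-tetraploid record ", id)
        skipped <- skipped + 1L
        next
      }
      dos <- dos[!is.na(dos)]
      if (length(dos) == 0L) {
        warning("skipping record with no called offspring: ", id)
        skipped <- skipped + 1L
        next
      }
      rec <- list(id = id, x = tabulate(dos + 1L, nbins = 5L))
      if (!is.null(parent_ids)) {
        pd <- vapply(gt[i, parent_ids], gt_dosage, integer(1))
        if (!any(is.na(pd))) {
          rec$ell1 <- pd[[1]]
          rec$ell2 <- pd[[2]]
        }
      }
    }
    records[[length(records) + 1L]] <- rec
  }
  structure(records, skipped = skipped)
}

#' Read per-SNP genotype counts from a CSV/TSV table
#'
#' Expects columns `marker`, `x0`..`x4`, `ell1`, `ell2` (header required;
#' comma- or tab-separated chosen by file extension).
#'
#' @param path Path to the table.
#' @return List of marker records (`id`, `x`, `ell1`, `ell2`).
#' @export
read_counts_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  needed <- c("marker", paste0("x", 0:4), "ell1", "ell2")
  if (nrow(tab) == 0L) {
    warning("empty counts table: ", path)
    return(list())
  }
  if (!all(needed %in% names(tab))) {
    stop("counts table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(tab)), function(i) {
    x <- as.numeric(tab[i, paste0("x", 0:4)])
    if (any(x < 0) || any(x != round(x))) {
      stop("negative or non-integer counts at marker ", tab$marker[i],
           call. = FALSE)
    }
    for (e in c(tab$ell1[i], tab$ell2[i])) stop_if_not_dosage(e)
    list(id = as.character(tab$marker[i]), x = x,
         ell1 = as.integer(tab$ell1[i]), ell2 = as.integer(tab$ell2[i]))
  })
}

## Maximum estimated genotype frequency of a record (monomorphic screen).
max_geno_freq <- function(rec) {
  if (!is.null(rec$x)) {
    max(rec$x) / sum(rec$x)
  } else {
    post <- rec$G / rowSums(rec$G)
    max(colMeans(post))
  }
}

#' Test a set of markers for segregation distortion
#'
#' Applies one of the segregation-distortion tests to every marker record
#' (as returned by [read_vcf()] or [read_counts_table()]) and returns a tidy
#' results table in input order, with Bonferroni- and Benjamini-Hochberg
#' adjusted p-values. Markers whose parental dosages are absent have them
#' estimated by maximum likelihood first. Optionally, near-monomorphic
#' markers (maximum estimated genotype frequency above `mono_threshold`) are
#' flagged and not tested.
#'
#' @param records List of marker records.
#' @param method One of `"lrt"`, `"bayes"`, `"chisq"`, `"polymapr"`.
#' @param dr_cap Maximum double reduction rate.
#' @param n_draws Monte Carlo draws for the Bayes test.
#' @param seed Optional seed for the Bayes test draws.
#' @param filter_monomorphic If `TRUE`, skip near-monomorphic markers.
#' @param mono_threshold Maximum-genotype-frequency threshold for the filter.
#' @return Data frame with one row per marker: `marker`, `method`, `stat`,
#'   `df`, `p_value`, `log_bf`, `mc_se`, `ell1_used`, `ell2_used`,
#'   `alpha_hat`, `xi1_hat`, `xi2_hat` (diagnostic only; unreliable at a
#'   single locus), `note`, and `p_bonferroni` / `p_bh` for p-value methods.
#' @export
seg_test_markers <- function(records, method = c("lrt", "bayes", "chisq", "polymapr"),
                             dr_cap = DR_CAP_DEFAULT, n_draws = 10000L,
                             seed = NULL, filter_monomorphic = FALSE,
                             mono_threshold = 0.95) {
  method <- match.arg(method)
  rows <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    row <- data.frame(
      marker = rec$id, method = method, stat = NA_real_, df = NA_integer_,
      p_value = NA_real_, log_bf = NA_real_, mc_se = NA_real_,
      ell1_used = NA_integer_, ell2_used = NA_integer_,
      alpha_hat = NA_real_, xi1_hat = NA_real_, xi2_hat = NA_real_,
      note = "", stringsAsFactors = FALSE
    )
    if (filter_monomorphic && max_geno_freq(rec) > mono_threshold) {
      row$note <- "monomorphic"
      return(row)
    }
    gl_mode <- is.null(rec$x)
    dat <- if (gl_mode) rec$G else rec$x
    have_parents <- !is.null(rec$ell1) && !is.null(rec$ell2)
    if (have_parents) {
      e1 <- rec$ell1; e2 <- rec$ell2
    } else {
      a <- if (!is.null(rec$a)) rec$a else rep(1, 5)
      b <- if (!is.null(rec$b)) rec$b else rep(1, 5)
      est <- estimate_parents(dat, a = a, b = b, dr_cap = dr_cap)
      e1 <- est[1]; e2 <- est[2]
      row$note <- "parents estimated"
    }
    row$ell1_used <- e1
    row$ell2_used <- e2
    if (method == "lrt") {
      r <- if (gl_mode) lrt_gl(dat, e1, e2, dr_cap = dr_cap) else
        lrt_counts(dat, e1, e2, dr_cap = dr_cap)
      row$stat <- r$stat; row$df <- r$df; row$p_value <- r$p_value
      if (!is.null(r$null_fit)) {
        row$alpha_hat <- r$null_fit$alpha
        row$xi1_hat <- r$null_fit$xi1
        row$xi2_hat <- r$null_fit$xi2
      }
    } else if (method == "bayes") {
      r <- bayes_test(dat, ell1 = e1, ell2 = e2,
                      prior = null_prior(dr_cap = dr_cap),
                      n_draws = n_draws, seed = seed)
      row$log_bf <- r$log_bf; row$mc_se <- r$mc_se
    } else if (method == "chisq") {
      xx <- if (gl_mode) post_mode_counts(dat) else dat
      r <- chisq_test(xx, e1, e2)
      row$stat <- r$details$stat; row$df <- r$details$df
      row$p_value <- r$p_value
    } else {
      dd <- if (gl_mode) dat / rowSums(dat) else dat
      r <- polymapr_like_test(dd, e1, e2)
      row$p_value <- r$p_value
    }
    row
  })
  res <- do.call(rbind, rows)
  if (any(!is.na(res$p_value))) {
    res$p_bonferroni <- pmin(res$p_value * sum(!is.na(res$p_value)), 1)
    res$p_bh <- stats::p.adjust(res$p_value, method = "BH")
  }
  res
}

#' Write a results table as tab-separated text
#'
#' @param results Data frame from [seg_test_markers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
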