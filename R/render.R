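# Display-convention rendering of stage outputs: frequencies to 3
# decimals, OR/CI to 3 decimals, P-values to 2 significant figures,
# pattern strings with "/" separators and "-" wildcards. Cells whose OR
# came from a Haldane-corrected table are flagged with "*".

fmt_freq <- function(x) sprintf("%.3f", x)
fmt_or <- function(x) sprintf("%.3f", x)
fmt_p <- function(p) {
  ifelse(is.na(p), "NA", formatC(signif(p, 2), format = "g"))
}
fmt_count_freq <- function(count, freq) sprintf("%d (%s)", count, fmt_freq(freq))
fmt_or_ci <- function(or, lo, hi, flag = FALSE) {
  ifelse(is.na(or), "-",
         sprintf("%s (%s-%s)%s", fmt_or(or), fmt_or(lo), fmt_or(hi),
                 ifelse(flag, "*", "")))
}

exposure_cells <- function(res) {
  if (is.null(res$exposure) || isTRUE(res$separated)) {
    return(c(p = "flagged", or_ci = "-"))
  }
  e <- res$exposure
  c(p = fmt_p(e$p_value), or_ci = fmt_or_ci(e$or, e$ci_lower, e$ci_upper))
}

render_table1 <- function(tab) {
  stopifnot(inherits(tab, "locus_table"))
  rows <- lapply(tab$reports, function(r) {
    gt_cells <- function(g) paste(mapply(fmt_count_freq, g$counts,
                                         g$counts / max(g$n_total, 1L)),
                                  collapse = "\t")
    states <- paste(names(r$genotypes$control$counts), collapse = "/")
    geno_p <- if (!is.null(r$models$genotypic)) {
      if (r$kind == "snp") fmt_p(r$models$genotypic$lrt_p)
      else exposure_cells(r$models$genotypic)[["p"]]
    } else ""
    if (r$kind == "snp") {
      al <- r$alleles
      allelic <- r$models$allelic
      data.frame(
        rsid = r$rsid, gene = r$gene, states = states,
        control_genotypes = gt_cells(r$genotypes$control),
        case_genotypes = gt_cells(r$genotypes$case),
        genotype_p = geno_p,
        control_alleles = paste(mapply(fmt_count_freq, al$control$counts,
                                       al$control$freq), collapse = "\t"),
        case_alleles = paste(mapply(fmt_count_freq, al$case$counts,
                                    al$case$freq), collapse = "\t"),
        allele_p = if (!is.null(allelic)) exposure_cells(allelic)[["p"]] else "",
        or_ci = if (!is.null(allelic)) {
          exposure_cells(allelic)[["or_ci"]]
        } else "",
        stringsAsFactors = FALSE)
    } else {
      dom <- r$models$dominant
      data.frame(
        rsid = r$rsid, gene = r$gene, states = states,
        control_genotypes = gt_cells(r$genotypes$control),
        case_genotypes = gt_cells(r$genotypes$case),
        genotype_p = if (!is.null(dom)) exposure_cells(dom)[["p"]] else "",
        control_alleles = "", case_alleles = "", allele_p = "",
        or_ci = if (!is.null(dom)) exposure_cells(dom)[["or_ci"]] else "",
        stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

render_table2 <- function(tab, loci) {
  stopifnot(inherits(tab, "locus_table"))
  rows <- list()
  for (r in tab$reports) {
    if (r$kind != "snp") next
    locus <- loci[loci$rsid == r$rsid, ]
    st <- locus_states(locus)
    labels <- c(
      dominant = sprintf("%s vs. %s + %s", st[["hom_ref"]], st[["het"]],
                         st[["hom_alt"]]),
      recessive = sprintf("%s + %s vs. %s", st[["hom_ref"]], st[["het"]],
                          st[["hom_alt"]]),
      additive = sprintf("%s vs. %s vs. %s", st[["hom_ref"]], st[["het"]],
                         st[["hom_alt"]]))
    for (m in c("dominant", "recessive", "additive")) {
      res <- r$models[[m]]
      if (is.null(res)) next
      cells <- exposure_cells(res)
      rows[[length(rows) + 1L]] <- data.frame(
        rsid = r$rsid, gene = r$gene, model = m, genotypes = labels[[m]],
        p = cells[["p"]], or_ci = cells[["or_ci"]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

combination_row <- function(res, loci, label) {
  counts <- res$counts
  ctrl <- counts[counts$group == "control", ]
  case <- counts[counts$group == "case", ]
  cells <- exposure_cells(res)
  data.frame(
    genotype = label,
    control = sprintf("%d (%s)", ctrl$carriers, fmt_freq(ctrl$frequency)),
    case = sprintf("%d (%s)", case$carriers, fmt_freq(case$frequency)),
    p = cells[["p"]], or_ci = cells[["or_ci"]], stringsAsFactors = FALSE)
}

render_table3 <- function(paths, strata, loci) {
  rows <- list(data.frame(genotype = character(0), control = character(0),
                          case = character(0), p = character(0),
                          or_ci = character(0), stringsAsFactors = FALSE))
  for (cls in names(paths)) {
    path <- paths[[cls]]
    header <- sprintf("%ss: %s", cls,
                      paste(names(path$steps[[1]]$pattern$slots),
                            collapse = "/"))
    rows[[length(rows) + 1L]] <- data.frame(
      genotype = header, control = "", case = "", p = "", or_ci = "",
      stringsAsFactors = FALSE)
    for (i in seq_along(path$steps)) {
      step <- path$steps[[i]]
      rows[[length(rows) + 1L]] <-
        combination_row(step, loci, pattern_string(step$pattern, loci))
      if (!is.null(strata[[cls]])) {
        rows[[length(rows) + 1L]] <-
          combination_row(strata[[cls]]$female[[i]], loci, "Female")
        rows[[length(rows) + 1L]] <-
          combination_row(strata[[cls]]$male[[i]], loci, "Male")
      }
    }
  }
  do.call(rbind, rows)
}

#' Render a stage result as a display table
#'
#' Formats stage outputs with the display conventions of the motivating
#' study's tables: `"table1"` renders a [locus_table()] as genotype/allele
#' frequencies with the genotypic and allelic P and the allelic OR;
#' `"table2"` renders the dominant/recessive/additive model results per
#' SNP locus; `"table3"` renders backward-elimination paths (a named list
#' of `elimination_path` per class, plus optional sex strata from
#' [stratified_results()]) as carrier counts, frequencies, P and OR rows.
#'
#' @param results Stage output matching `style`.
#' @param style One of `"table1"`, `"table2"`, `"table3"`.
#' @param loci Locus-definition table (needed for state labels).
#' @param strata Optional named list (per class) of [stratified_results()]
#'   output, for `"table3"`.
#' @return A character `data.frame` ready to write as TSV.
#' @export
render_table <- function(results, style = c("table1", "table2", "table3"),
                         loci = NULL, strata = NULL) {
  style <- match.arg(style)
  switch(style,
    table1 = {
      if (!inherits(results, "locus_table")) {
        stop("render_table: style 'table1' needs a locus_table")
      }
      render_table1(results)
    },
    table2 = {
      if (!inherits(results, "locus_table")) {
        stop("render_table: style 'table2' needs a locus_table")
      }
      if (is.null(loci)) stop("render_table: 'loci' required for table2")
      render_table2(results, loci)
    },
    table3 = {
      if (!is.list(results) ||
          !all(vapply(results, inherits, logical(1), "elimination_path"))) {
        stop("render_table: style 'table3' needs a named list of ",
             "elimination_path objects")
      }
      if (is.null(loci)) stop("render_table: 'loci' required for table3")
      render_table3(results, strata, loci)
    })
}

#' Render a grouping footnote
#'
#' @param groupings Named list from [derive_groupings()].
#' @return Single string in the style
#'   `"TT + TC and CC for rs12441817, ..."`.
#' @export
grouping_footnote <- function(groupings) {
  parts <- vapply(groupings, function(g) {
    sprintf("%s and %s for %s", paste(g$group1, collapse = " + "),
            paste(g$group2, collapse = " + "), g$rsid)
  }, character(1))
  paste(parts, collapse = ", ")
}
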