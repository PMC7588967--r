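# Grouped statistical comparisons of SS and energy values, with the
# conventional significance-star scheme. The test family is Welch's
# unequal-variance two-sided unpaired t-test by default (replicate windows
# have no natural pairing); the pooled Student variant is available behind
# `var_equal = TRUE`. Framewise window values within one trajectory are
# autocorrelated; treating frames as observations is the field's
# convention, reproduced here, with optional block averaging as a
# conservative pre-step.

#' Welch's t-test
#'
#' Unequal-variance, unpaired, two-sided by default. When both samples have
#' zero variance and equal means, `p = 1` by convention (no evidence of a
#' difference); zero variance in both with different means is a
#' degenerate-input error.
#'
#' @param a,b numeric samples, each of length >= 2, finite.
#' @param var_equal use the pooled-variance Student variant instead.
#' @return list with `t_stat`, `df` (Welch-Satterthwaite), `p_value`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
welch_t_test <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite values")
  base <- list(mean_a = mean(a), mean_b = mean(b),
               n_a = length(a), n_b = length(b))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(c(list(t_stat = 0, df = length(a) + length(b) - 2, p_value = 1),
               base))
    }
    stop("degenerate input: both samples constant with different means")
  }
  tt <- stats::t.test(a, b, var.equal = var_equal, paired = FALSE,
                      alternative = "two.sided")
  c(list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value), base)
}

#' Map a p-value to significance stars
#'
#' The conventional scheme: `ns` for p > 0.05; `*` for p <= 0.05; `**` for
#' p <= 0.01; `***` for p <= 0.001; `****` for p <= 0.0001 (boundaries
#' inclusive toward more stars).
#'
#' @param p_value numeric vector of p-values in `[0, 1]`.
#' @return character vector in `{ns, *, **, ***, ****}`.
#' @export
significance_stars <- function(p_value) {
  if (any(!is.finite(p_value)) || any(p_value < 0) || any(p_value > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  vapply(p_value, function(p) {
    if (p <= 1e-4) "****"
    else if (p <= 1e-3) "***"
    else if (p <= 0.01) "**"
    else if (p <= 0.05) "*"
    else "ns"
  }, character(1))
}

#' Parse a ligand code
#'
#' Nomenclature: optional prefix `m` = isoxazole mimic (absent = natural
#' poly-beta-ketone); body `tet` (tetraketide, 8 carbons) or `oct`
#' (octaketide, 16 carbons); optional suffix `p` = pantetheine or `pp` =
#' phosphopantetheine (absent = polyketide moiety only). Unknown codes are
#' rejected.
#'
#' @param code character, e.g. `"m-oct-pp"`, `"tet-p"`, `"oct"`.
#' @return list with `mimic` (logical), `ketide` (`"tet"`/`"oct"`),
#'   `arm` (`"p"`, `"pp"` or `NA`).
#' @export
parse_ligand_code <- function(code) {
  m <- regmatches(code, regexec("^(m-)?(tet|oct)(-(pp|p))?$", code))[[1L]]
  if (length(m) == 0L) stop("unknown ligand code: ", code)
  list(mimic = m[2L] == "m-", ketide = m[3L],
       arm = if (nzchar(m[5L])) m[5L] else NA_character_)
}

#' Average a framewise window in non-overlapping blocks
#'
#' Conservative pre-step that reduces the autocorrelation of framewise
#' values before testing; a trailing partial block is dropped.
#'
#' @param values numeric vector of framewise values.
#' @param block_size frames per block (>= 1).
#' @return numeric vector of block means.
#' @export
block_average <- function(values, block_size) {
  stopifnot(block_size >= 1L)
  n_blocks <- length(values) %/% block_size
  if (n_blocks < 1L) stop("fewer values than one block")
  idx <- rep(seq_len(n_blocks), each = block_size)
  as.numeric(tapply(values[seq_len(n_blocks * block_size)], idx, mean))
}

.compare_cells <- function(a, b, label_a, label_b, group, var_equal,
                           block_size) {
  if (!is.null(block_size)) {
    a <- block_average(a, block_size)
    b <- block_average(b, block_size)
  }
  if (length(a) < 2L || length(b) < 2L) {
    warning("skipping ", group, ": ", label_a, " vs ", label_b,
            " (a cell has fewer than 2 values)", call. = FALSE)
    return(NULL)
  }
  tt <- welch_t_test(a, b, var_equal = var_equal)
  data.frame(
    group = group, group_a = label_a, group_b = label_b,
    n_a = tt$n_a, n_b = tt$n_b, mean_a = tt$mean_a, mean_b = tt$mean_b,
    t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value,
    direction = sign(tt$mean_a - tt$mean_b),
    stringsAsFactors = FALSE
  )
}

#' Grouped pairwise comparisons of window values
#'
#' Three groupings mirror the study design:
#' \describe{
#'   \item{`by-binding-site`}{per ligand: front-patch vs back-patch
#'     windows.}
#'   \item{`by-kr-type`}{per ligand: every pair of KR types present
#'     (e.g. DM-ActKR vs WT-ActKR vs WT-HedKR).}
#'   \item{`by-phosphorylation`}{per KR type and ketide body: pantetheine
#'     (`-p`) vs phosphopantetheine (`-pp`) ligand forms.}
#' }
#' Cells with fewer than 2 values are skipped with a warning. No
#' multiple-testing correction is applied by default (per-panel star
#' reporting); `p_adjust = "BH"` adds Benjamini-Hochberg adjusted p-values
#' and stars them instead.
#'
#' @param data data.frame with columns `ligand`, `kr_type`, `binding_site`,
#'   `replicate`, `value` (one row per window frame).
#' @param grouping one of `"by-binding-site"`, `"by-kr-type"`,
#'   `"by-phosphorylation"`.
#' @param var_equal pooled-variance Student test instead of Welch.
#' @param block_size optional block-averaging size (frames) applied to each
#'   cell before testing.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return data.frame of comparison results sorted by (group, pair), with
#'   significance `stars`.
#' @export
grouped_comparison <- function(data,
                               grouping = c("by-binding-site", "by-kr-type",
                                            "by-phosphorylation"),
                               var_equal = FALSE, block_size = NULL,
                               p_adjust = c("none", "BH")) {
  grouping <- match.arg(grouping)
  p_adjust <- match.arg(p_adjust)
  needed <- c("ligand", "kr_type", "binding_site", "replicate", "value")
  stopifnot(all(needed %in% names(data)))
  rows <- list()
  if (grouping == "by-binding-site") {
    for (lig in sort(unique(data$ligand))) {
      d <- data[data$ligand == lig, ]
      rows[[length(rows) + 1L]] <- .compare_cells(
        d$value[d$binding_site == "front"], d$value[d$binding_site == "back"],
        "front", "back", lig, var_equal, block_size
      )
    }
  } else if (grouping == "by-kr-type") {
    for (lig in sort(unique(data$ligand))) {
      d <- data[data$ligand == lig, ]
      types <- sort(unique(d$kr_type))
      if (length(types) < 2L) next
      cmb <- utils::combn(types, 2L)
      for (k in seq_len(ncol(cmb))) {
        rows[[length(rows) + 1L]] <- .compare_cells(
          d$value[d$kr_type == cmb[1L, k]], d$value[d$kr_type == cmb[2L, k]],
          cmb[1L, k], cmb[2L, k], lig, var_equal, block_size
        )
      }
    }
  } else {
    data$ketide <- vapply(data$ligand,
                          function(l) parse_ligand_code(l)$ketide,
                          character(1))
    data$arm <- vapply(data$ligand,
                       function(l) parse_ligand_code(l)$arm,
                       character(1))
    for (kr in sort(unique(data$kr_type))) {
      for (kt in sort(unique(data$ketide))) {
        d <- data[data$kr_type == kr & data$ketide == kt, ]
        rows[[length(rows) + 1L]] <- .compare_cells(
          d$value[!is.na(d$arm) & d$arm == "pp"],
          d$value[!is.na(d$arm) & d$arm == "p"],
          "pp", "p", paste(kr, kt, sep = ":"), var_equal, block_size
        )
      }
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("no comparable cells for grouping ", grouping)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$group_a, out$group_b), , drop = FALSE]
  rownames(out) <- NULL
  if (p_adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$stars <- significance_stars(out$p_adjusted)
  } else {
    out$stars <- significance_stars(out$p_value)
  }
  out
}
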