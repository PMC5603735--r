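#' Define a simulation scenario for one gene
#'
#' A gene setting bundles the per-variant population minor allele
#' frequencies and relative risks with the case-control design used to
#' simulate it: `n_cases` cases, `n_controls` controls, and the Step-1
#' significance level `alpha`.
#'
#' @param maf Numeric vector of population minor allele frequencies, one per
#'   variant, each in (0, 0.5].
#' @param rr Numeric vector of per-variant relative risks (> 0); `rr = 1` is
#'   a neutral variant.
#' @param n_cases,n_controls Numbers of cases and controls.
#' @param alpha Step-1 significance level in (0, 1).
#' @param setting_id Character label for the setting.
#' @param variant_ids Optional character vector of variant labels; defaults
#'   to `snp1 ... snpm`.
#'
#' @return An object of class `gene_setting`: a list with fields
#'   `setting_id`, `maf`, `rr`, `n_cases`, `n_controls`, `alpha`,
#'   `variant_ids`.
#' @seealso [canonical_settings()], [simulate_gene()], [expected_values()]
#' @export
#' @examples
#' gene_setting(maf = c(rep(1e-4, 5), 0.01, rep(1e-4, 4)),
#'              rr  = c(rep(8, 5), rep(1, 5)))
gene_setting <- function(maf, rr, n_cases = 1500, n_controls = 1500,
                         alpha = 0.01, setting_id = "setting",
                         variant_ids = NULL) {
  if (length(maf) != length(rr) || length(maf) < 1L)
    stop("`maf` and `rr` must have equal, positive length", call. = FALSE)
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5))
    stop("all `maf` must lie in (0, 0.5]", call. = FALSE)
  if (any(!is.finite(rr)) || any(rr <= 0))
    stop("all `rr` must be > 0", call. = FALSE)
  if (n_cases < 1 || n_controls < 1)
    stop("`n_cases` and `n_controls` must be >= 1", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (is.null(variant_ids)) variant_ids <- paste0("snp", seq_along(maf))
  if (anyDuplicated(variant_ids))
    stop("`variant_ids` must be unique", call. = FALSE)
  structure(list(setting_id = as.character(setting_id),
                 maf = as.double(maf), rr = as.double(rr),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 alpha = as.double(alpha),
                 variant_ids = as.character(variant_ids)),
            class = "gene_setting")
}

#' @export
print.gene_setting <- function(x, ...) {
  cat("Gene setting '", x$setting_id, "': ", length(x$maf), " variants, ",
      x$n_cases, " cases / ", x$n_controls, " controls, alpha = ",
      x$alpha, "\n", sep = "")
  print(data.frame(variant = x$variant_ids, maf = x$maf, rr = x$rr),
        row.names = FALSE)
  invisible(x)
}

# Relative risk assigned to a risk-increasing variant of frequency f; the
# rarer the variant the larger the effect (risk-decreasing variants use the
# reciprocal).
risk_lambda <- function(f) {
  levels <- c(0.05, 0.01, 0.001, 0.0001)
  lam <- c(1.2, 1.5, 2, 8)[match(f, levels)]
  if (anyNA(lam))
    stop("no canonical relative risk defined for MAF ", f[is.na(lam)][1],
         call. = FALSE)
  lam
}

#' The canonical catalogue of 50 simulation settings
#'
#' Builds the full grid of 10 minor-allele-frequency architectures crossed
#' with 5 relative-risk mixes, each a 10-variant gene studied with 1,500
#' cases and 1,500 controls:
#' \itemize{
#'   \item architecture `a`: all 10 variants rare (all `f` = 0.0001 or all
#'     0.001);
#'   \item architecture `b`: one common neutral variant (`f` = 0.05 or 0.01)
#'     plus 9 rare variants (0.0001 or 0.001);
#'   \item architecture `c`: two common variants (one neutral, one
#'     risk-increasing when the mix allows) plus 8 rare variants.
#' }
#' Relative-risk mixes give the percentage of variants that are
#' risk-increasing : neutral : risk-decreasing -- 20:80:0, 50:50:0, 80:20:0,
#' 20:60:20 and 0:100:0 (the fully null mix).  Risk-increasing relative
#' risks depend on frequency: (0.05, 1.2), (0.01, 1.5), (0.001, 2),
#' (0.0001, 8); risk-decreasing effects are the reciprocals.
#'
#' Variants within a setting are ordered: risk-increasing rare, common
#' (risk-increasing common first), neutral rare, risk-decreasing rare.
#'
#' @param n_cases,n_controls,alpha Design shared by every setting.
#' @return A named list of 50 [gene_setting()] objects.
#' @export
canonical_settings <- function(n_cases = 1500, n_controls = 1500,
                               alpha = 0.01) {
  rare_levels <- c(0.0001, 0.001)
  common_levels <- c(0.05, 0.01)
  archs <- list()
  for (fr in rare_levels)
    archs[[length(archs) + 1L]] <-
      list(class = "a", rare = fr, common = numeric(0), common_causal = FALSE)
  for (fc in common_levels) for (fr in rare_levels)
    archs[[length(archs) + 1L]] <-
      list(class = "b", rare = fr, common = fc, common_causal = FALSE)
  for (fc in common_levels) for (fr in rare_levels)
    archs[[length(archs) + 1L]] <-
      list(class = "c", rare = fr, common = fc, common_causal = TRUE)
  mixes <- list(c(20, 80, 0), c(50, 50, 0), c(80, 20, 0),
                c(20, 60, 20), c(0, 100, 0))

  out <- list()
  for (arch in archs) {
    n_common <- length(arch$common) + if (arch$common_causal) 1L else 0L
    for (mix in mixes) {
      m <- 10L
      n_up <- as.integer(round(m * mix[1] / 100))
      n_down <- as.integer(round(m * mix[3] / 100))
      # A designated risk-increasing common variant occupies one of the
      # risk-increasing slots; under the fully null mix it is neutral.
      common_up <- arch$common_causal && n_up >= 1L
      fc <- if (arch$class == "a") numeric(0) else arch$common
      n_rare <- m - n_common
      n_up_rare <- n_up - if (common_up) 1L else 0L
      n_neut_rare <- n_rare - n_up_rare - n_down
      stopifnot(n_up_rare >= 0L, n_neut_rare >= 0L)

      maf <- c(rep(arch$rare, n_up_rare),
               if (common_up) fc,
               if (n_common > 0L) rep(fc, n_common - if (common_up) 1L else 0L),
               rep(arch$rare, n_neut_rare),
               rep(arch$rare, n_down))
      rr <- c(rep(risk_lambda(arch$rare), n_up_rare),
              if (common_up) risk_lambda(fc),
              if (n_common > 0L) rep(1, n_common - if (common_up) 1L else 0L),
              rep(1, n_neut_rare),
              rep(1 / risk_lambda(arch$rare), n_down))

      id <- sprintf("%s_rare%s%s_%d:%d:%d", arch$class,
                    format(arch$rare, scientific = FALSE),
                    if (arch$class == "a") ""
                    else paste0("_common", format(arch$common, scientific = FALSE)),
                    mix[1], mix[2], mix[3])
      out[[id]] <- gene_setting(maf, rr, n_cases, n_controls, alpha,
                                setting_id = id)
    }
  }
  out
}

#' Write or read a settings catalogue as YAML
#'
#' Each setting is serialised with its fields verbatim, one list entry per
#' setting, so catalogues can be edited by hand and shared between runs.
#'
#' @param settings A list of [gene_setting()] objects (or a single one).
#' @param path File path.
#' @return `read_settings()` returns a named list of `gene_setting` objects;
#'   `write_settings()` returns `path` invisibly.
#' @export
write_settings <- function(settings, path) {
  if (inherits(settings, "gene_setting")) settings <- list(settings)
  docs <- lapply(settings, function(s) {
    list(setting_id = s$setting_id, maf = s$maf, rr = s$rr,
         n_cases = s$n_cases, n_controls = s$n_controls, alpha = s$alpha,
         variant_ids = s$variant_ids)
  })
  yaml::write_yaml(unname(docs), path)
  invisible(path)
}

#' @rdname write_settings
#' @export
read_settings <- function(path) {
  docs <- yaml::read_yaml(path)
  out <- lapply(docs, function(d) {
    gene_setting(maf = unlist(d$maf), rr = unlist(d$rr),
                 n_cases = d$n_cases, n_controls = d$n_controls,
                 alpha = d$alpha, setting_id = d$setting_id,
                 variant_ids = unlist(d$variant_ids))
  })
  names(out) <- vapply(out, function(s) s$setting_id, character(1))
  out
}
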