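#' Domain scores from raw Child-Functioning-Module items
#'
#' Disability items are severity codes 1-4 ("no difficulty" = 1, "some
#' difficulty" = 2, "a lot of difficulty" = 3, "cannot do at all" = 4);
#' well-being items are frequency codes 1-5 ("never" = 1 ... "daily" = 5).
#' Domains asked through several sub-questions are scored as the sub-item
#' sum rescaled so that the maximum attainable value is 4 — which, for items
#' on the common 1-4 scale, equals the item mean. Single-item domains pass
#' through; a missing sub-item propagates a missing domain score.
#'
#' @param data Tibble of raw item responses.
#' @param domains Named list: domain name -> character vector of item
#'   columns.
#' @param item_max Named vector of maximum valid code per item (defaults to
#'   4 for every item not listed).
#' @return `data` with the item columns replaced by one score column per
#'   domain.
#' @export
#' @examples
#' raw <- tibble::tibble(rem_1 = c(1, 4), rem_2 = c(3, 4))
#' derive_domain_scores(raw, list(remembering_concentrating = c("rem_1", "rem_2")))
derive_domain_scores <- function(data, domains, item_max = NULL) {
  items <- unlist(domains, use.names = FALSE)
  missing_items <- setdiff(items, names(data))
  if (length(missing_items))
    abort(paste0("item columns not found: ",
                 paste(missing_items, collapse = ", ")))
  for (it in items) {
    mx <- if (!is.null(item_max) && it %in% names(item_max))
      item_max[[it]] else 4
    x <- data[[it]]
    bad <- which(!is.na(x) & (x < 1 | x > mx | x != round(x)))
    if (length(bad))
      abort(sprintf("out-of-range code in column '%s', row %d (value %s)",
                    it, bad[1], format(x[bad[1]])))
  }
  scores <- purrr::imap(domains, function(cols, dom) {
    sub <- as.matrix(data[cols])
    if (length(cols) == 1L) return(as.numeric(sub[, 1]))
    # sum rescaled to a maximum of 4: sum * 4 / (4 * k) = mean on a 1-4 scale
    rowSums(sub) * 4 / (4 * length(cols))
  })
  out <- data[setdiff(names(data), items)]
  dplyr::bind_cols(out, tibble::as_tibble(scores))
}

#' Functional-disability eligibility flag
#'
#' A respondent is flagged as having a functional disability when "a lot of
#' difficulty" or "cannot do at all" (codes 3 or 4) is reported on at least
#' one disability domain. Well-being items never enter the rule. Respondents
#' with all observed codes below 3 but some missing domains get `NA`.
#'
#' @param data Survey tibble.
#' @param items Disability item/domain columns (default: the CFM disability
#'   community).
#' @return Logical vector, one element per respondent.
#' @export
flag_functional_disability <- function(data,
                                       items = dplyr::filter(
                                         cfm_communities(),
                                         .data$community == "disability")$node) {
  missing_items <- setdiff(items, names(data))
  if (length(missing_items))
    abort(paste0("disability columns not found: ",
                 paste(missing_items, collapse = ", ")))
  X <- as.matrix(data[items])
  any3 <- apply(X >= 3, 1, function(r) {
    if (any(r, na.rm = TRUE)) TRUE else if (anyNA(r)) NA else FALSE
  })
  as.logical(any3)
}

#' Weighted descriptive statistics with between-group tests
#'
#' Weighted means and standard deviations for continuous variables,
#' weighted counts and percentages (one decimal) for categoricals, plus
#' two-tailed t-test / Pearson chi-squared p-values for the group contrast.
#' A constant variable yields an undefined (NA) statistic rather than an
#' error.
#'
#' @param data Survey tibble.
#' @param group_var Grouping column (two levels).
#' @param continuous,categorical Character vectors of variable names.
#' @param weights Weight column (or `NULL`).
#' @return A tibble: `variable`, `level` (categoricals), per-group
#'   statistics, `test`, `p_value`.
#' @export
descriptives <- function(data, group_var, continuous = character(),
                         categorical = character(), weights = "weight") {
  g <- factor(data[[group_var]])
  if (nlevels(g) < 2) abort("descriptives needs at least 2 groups")
  w <- if (is.null(weights)) rep(1, nrow(data)) else as.numeric(data[[weights]])
  lv <- levels(g)

  cont <- purrr::map_dfr(continuous, function(v) {
    x <- as.numeric(data[[v]])
    stats <- purrr::map_dfr(lv, function(l) {
      i <- which(g == l & !is.na(x))
      m <- sum(w[i] * x[i]) / sum(w[i])
      s2 <- sum(w[i] * (x[i] - m)^2) / max(sum(w[i]) - 1, 1)
      tibble::tibble(group = l, mean = m, sd = sqrt(s2))
    })
    p <- tryCatch(
      stats::t.test(x[g == lv[1]], x[g == lv[2]])$p.value,
      error = function(e) NA_real_)
    tibble::tibble(
      variable = v, level = NA_character_, test = "t",
      stat_group1 = sprintf("%.2f (%.2f)", stats$mean[1], stats$sd[1]),
      stat_group2 = sprintf("%.2f (%.2f)", stats$mean[2], stats$sd[2]),
      p_value = p)
  })

  cat_tbl <- purrr::map_dfr(categorical, function(v) {
    x <- factor(data[[v]])
    tab <- table(x, g)
    p <- tryCatch(
      stats::chisq.test(tab, correct = FALSE)$p.value,
      error = function(e) NA_real_)
    purrr::map_dfr(levels(x), function(l) {
      n1 <- sum(w[x == l & g == lv[1]], na.rm = TRUE)
      n2 <- sum(w[x == l & g == lv[2]], na.rm = TRUE)
      tibble::tibble(
        variable = v, level = l, test = "chisq",
        stat_group1 = sprintf("%.0f (%.1f%%)", n1,
                              100 * n1 / sum(w[g == lv[1]], na.rm = TRUE)),
        stat_group2 = sprintf("%.0f (%.1f%%)", n2,
                              100 * n2 / sum(w[g == lv[2]], na.rm = TRUE)),
        p_value = p)
    })
  })
  dplyr::bind_rows(cont, cat_tbl)
}

#' Full analysis configuration
#'
#' Defaults follow the study design: EBIC hyperparameter `gamma = 0.5`,
#' 5000 bootstrap resamples of each flavour, 10 chained-equation
#' imputations, significance level `alpha = 0.05`. Round-trips through JSON
#' unchanged (see [write_config()]).
#'
#' @inheritParams estimator_config
#' @param n_boot,n_permutations,drop_grid,m_imputations,alpha,group_vars
#'   Analysis-stage settings.
#' @param seed Master seed for [run_study()].
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(method = "pearson", missing = "pairwise",
                            gamma = 0.5, n_lambda = 100,
                            lambda_min_ratio = 0.01,
                            n_boot = 5000, n_permutations = 1000,
                            drop_grid = seq(0.05, 0.75, by = 0.1),
                            m_imputations = 10, alpha = 0.05,
                            group_vars = c("gender", "age_group"),
                            seed = 1) {
  structure(
    list(method = method, missing = missing, gamma = gamma,
         n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
         n_boot = n_boot, n_permutations = n_permutations,
         drop_grid = drop_grid, m_imputations = m_imputations,
         alpha = alpha, group_vars = group_vars, seed = seed),
    class = "analysis_config"
  )
}

as_estimator_config <- function(cfg) {
  estimator_config(method = cfg$method, missing = cfg$missing,
                   gamma = cfg$gamma, n_lambda = cfg$n_lambda,
                   lambda_min_ratio = cfg$lambda_min_ratio)
}

#' Write / read an analysis configuration as JSON
#'
#' @param config An [analysis_config()].
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(analysis_config, raw)
}

#' Run the complete study pipeline
#'
#' Mirrors the analysis flow end to end on one survey table: schema
#' validation, eligibility filtering, listwise exclusion for the primary
#' analysis, weighted descriptives by gender, gender-split networks with
#' bridge centralities and a gender permutation comparison, age-split
#' comparisons within each gender, bootstrap and case-dropping robustness
#' per gender network, and the chained-imputation sensitivity network on the
#' unexcluded data. Every output is a file under `output_dir`, indexed by a
#' single `manifest.json` holding the config, the seed and an MD5 per file —
#' rerunning with the same seed reproduces every byte.
#'
#' @param data Survey tibble (typically from [simulate_survey()] or
#'   [read_survey()]).
#' @param config An [analysis_config()].
#' @param output_dir Directory for outputs (created if needed).
#' @param communities Community map.
#' @param filter_eligible Keep only respondents flagged by
#'   [flag_functional_disability()]? Defaults to `FALSE` because the
#'   synthetic generator draws from the disability-population model
#'   directly.
#' @return The manifest, invisibly, as a list.
#' @export
run_study <- function(data, config = analysis_config(), output_dir,
                      communities = cfm_communities(),
                      filter_eligible = FALSE) {
  check_schema(data, communities)
  for (v in config$group_vars)
    if (!v %in% names(data)) abort(paste0("grouping column missing: ", v))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  est <- as_estimator_config(config)
  gender_var <- config$group_vars[1]
  age_var <- if (length(config$group_vars) > 1) config$group_vars[2] else NULL
  files <- character(0)
  add <- function(path) files <<- c(files, path)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e))))
    message(sprintf("[%s] %.1fs", name, proc.time()[["elapsed"]] - t0))
    res
  }

  if (filter_eligible) {
    flag <- flag_functional_disability(data)
    data <- data[!is.na(flag) & flag, , drop = FALSE]
  }
  # primary analysis: listwise exclusion of incomplete cases
  complete <- data[complete.cases(data[communities$node]), , drop = FALSE]

  seeds <- config$seed + seq_len(20)  # per-stage sub-seeds

  stage("descriptives", {
    desc <- descriptives(
      complete, gender_var,
      continuous = communities$node[communities$community != "confounder"],
      categorical = character(0))
    f <- file.path(output_dir, "descriptives.csv")
    write.csv(desc, f, row.names = FALSE, na = ""); add(f)
  })

  genders <- sort(unique(as.character(complete[[gender_var]])))
  nets <- list()
  for (g in genders) {
    sub <- complete[complete[[gender_var]] == g, , drop = FALSE]
    net <- stage(paste0("network_", g),
                 estimate_network(sub, communities, config = est))
    nets[[g]] <- net
    base <- file.path(output_dir, paste0("network_", g))
    write_network(net, base)
    add(paste0(base, c("_matrix.csv", "_edges.csv", "_provenance.json")))
    f <- file.path(output_dir, paste0("centrality_", g, ".csv"))
    write_centrality(centrality(net), f); add(f)
  }

  cmp_gender <- stage("comparison_gender",
    network_compare(complete, gender_var, groups = genders,
                    communities = communities, config = est,
                    n_permutations = config$n_permutations,
                    seed = seeds[1]))
  base <- file.path(output_dir, "comparison_gender")
  write_comparison(cmp_gender, base)
  add(paste0(base, c(".json", "_nodes.csv")))

  if (!is.null(age_var)) {
    for (i in seq_along(genders)) {
      g <- genders[i]
      sub <- complete[complete[[gender_var]] == g, , drop = FALSE]
      ages <- sort(unique(as.character(sub[[age_var]])))
      for (a in ages) {
        net <- stage(paste0("network_", g, "_", a),
          estimate_network(sub[sub[[age_var]] == a, , drop = FALSE],
                           communities, config = est))
        base <- file.path(output_dir, paste0("network_", g, "_", a))
        write_network(net, base)
        add(paste0(base, c("_matrix.csv", "_edges.csv", "_provenance.json")))
      }
      cmp <- stage(paste0("comparison_age_", g),
        network_compare(sub, age_var, groups = ages,
                        communities = communities, config = est,
                        n_permutations = config$n_permutations,
                        seed = seeds[1 + i]))
      base <- file.path(output_dir, paste0("comparison_age_", g))
      write_comparison(cmp, base)
      add(paste0(base, c(".json", "_nodes.csv")))
    }
  }

  for (i in seq_along(genders)) {
    g <- genders[i]
    sub <- complete[complete[[gender_var]] == g, , drop = FALSE]
    bt <- stage(paste0("bootstrap_", g),
      bootstrap_network(sub, communities, config = est,
                        n_boot = config$n_boot, seed = seeds[5 + i]))
    f <- file.path(output_dir, paste0("bootstrap_", g, ".csv"))
    write_bootstrap(bt, f); add(f)
    st <- stage(paste0("stability_", g),
      case_dropping_stability(sub, communities, config = est,
                              drop_grid = config$drop_grid,
                              n_boot = config$n_boot, seed = seeds[8 + i]))
    f <- file.path(output_dir, paste0("stability_", g, ".json"))
    write_stability(st, f); add(f)
  }

  if (anyNA(data[communities$node])) {
    imp <- stage("imputation",
      impute_chained(data, communities, m = config$m_imputations,
                     seed = seeds[12]))
    for (g in genders) {
      keep <- data[[gender_var]] == g
      sub_imp <- imp
      sub_imp$tables <- purrr::map(imp$tables, ~ .x[keep, , drop = FALSE])
      net <- stage(paste0("imputation_network_", g),
                   pooled_network(sub_imp, communities, config = est))
      base <- file.path(output_dir, paste0("imputation_network_", g))
      write_network(net, base)
      add(paste0(base, c("_matrix.csv", "_edges.csv", "_provenance.json")))
    }
  }

  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    n_input = nrow(data), n_complete = nrow(complete),
    files = lapply(sort(files), function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
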