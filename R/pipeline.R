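#' @include AllClasses.R
NULL

CONFIG_KEYS <- c("label", "inputs", "scale", "aliases", "units", "subsets",
                 "kGrid", "levittExponent", "sigmaDivisor", "outputDir",
                 "seed")
SUBSET_KEYS <- c("interface", "ligands", "ss", "zones", "sheets", "custom")

resolveScale <- function(scale) {
  if (is.null(scale) || identical(scale, "kd") ||
      identical(scale, "kyte-doolittle"))
    return(list(scale = kyteDoolittleScale(), name = "kyte-doolittle (min-max normalised)"))
  if (is.character(scale) && length(scale) == 1L && file.exists(scale)) {
    df <- utils::read.table(scale, header = TRUE, stringsAsFactors = FALSE)
    v <- stats::setNames(df[[2]], df[[1]])
    return(list(scale = checkScale(v), name = scale))
  }
  if (is.list(scale)) scale <- unlist(scale)
  list(scale = checkScale(scale), name = "user-supplied")
}

validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config error: config must be a list or YAML path")
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$inputs) || !length(config$inputs))
    stop("config error: no inputs")
  if (is.null(config$units) || !length(config$units))
    stop("config error: empty unit list")
  if (!is.null(config$subsets)) {
    bad <- setdiff(names(config$subsets), SUBSET_KEYS)
    if (length(bad))
      stop("config error: unknown subset key(s): ", paste(bad, collapse = ", "))
  }
  config$label <- config$label %||% "run"
  config$kGrid <- utils::modifyList(list(kMax = 10, step = 0.1),
                                    config$kGrid %||% list())
  config$levittExponent <- config$levittExponent %||% 8
  if (!config$levittExponent %in% c(8, 9))
    stop("config error: levittExponent must be 8 or 9")
  config$sigmaDivisor <- config$sigmaDivisor %||% 3
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## build the unit a selector describes; NULL chains+ranges = whole complex
selectorUnit <- function(structure, sel) {
  ranges <- if (!is.null(sel$ranges))
    do.call(rbind, lapply(sel$ranges, as.data.frame))
  makeUnit(structure, chains = unlist(sel$chains), ranges = ranges,
           label = sel$label %||% "complex")
}

subsetResults <- function(structure, unit, t, o, subsets, kGrid, log) {
  out <- list()
  runOne <- function(spec) {
    tryCatch({
      r <- fragmentStatus(t, o, spec, kMax = kGrid$kMax, step = kGrid$step)
      out[[length(out) + 1L]] <<- r
      log(sprintf("%s / %s: N=%d RD=%.3f K=%.1f", r@unitLabel, r@subsetLabel,
                  r@n, r@rd, r@kOpt))
    }, error = function(e) {
      log(sprintf("%s / %s: ERROR %s", unit@label, subsetLabel(spec),
                  conditionMessage(e)))
    })
  }
  ## each subset family fails independently: the error is logged with its
  ## unit context and the remaining work continues
  contained <- function(tag, expr) {
    tryCatch(expr, error = function(e) {
      log(sprintf("%s / %s: ERROR %s", unit@label, tag, conditionMessage(e)))
    })
  }
  if (!is.null(subsets$interface)) contained("interface", {
    pr <- interchainInterface(structure, unit, subsets$interface$cutoff %||% 5.0)
    runOne(pr$pp); runOne(pr$noPp)
  })
  if (!is.null(subsets$ligands)) contained("ligands", {
    pr <- ligandContacts(structure, unit, subsets$ligands$cutoff %||% 5.0,
                         unlist(subsets$ligands$names))
    runOne(pr$pLigand); runOne(pr$noLigand)
  })
  if (isTRUE(subsets$ss)) contained("ss", {
    for (s in ssSegments(structure, unit)) runOne(s)
  })
  if (!is.null(subsets$zones)) contained("zones", {
    z <- subsets$zones
    zs <- zoneAssignment(unit, axis = unlist(z$axis) %||% c(0, 0, 1),
                         zLo = z$zLo, zHi = z$zHi,
                         externalSide = z$externalSide %||% "+")
    for (s in zs) runOne(s)
  })
  if (!is.null(subsets$sheets)) contained("sheets", {
    ov <- if (!is.null(subsets$sheets$override))
      do.call(rbind, lapply(subsets$sheets$override, as.data.frame))
    for (s in sheetSegments(structure, unit, override = ov)) runOne(s)
  })
  if (!is.null(subsets$custom)) contained("custom", {
    for (cs in subsets$custom)
      runOne(newSubset(cs$label %||% "custom", unlist(cs$mask)))
  })
  out
}

#' Run the full analysis pipeline from a configuration
#'
#' For each input structure and each unit selector: fit the Gaussian field,
#' compute the T/O/R profiles, optimise K and collect the divergence
#' statistics; then score every configured residue subset by renormalisation.
#' A failing subset is logged with its unit context and the run continues.
#' The report carries a decision log naming every default the run relied on
#' and an md5 hash of each input, so identical config + inputs give
#' identical numbers.
#'
#' @param config a list or a YAML file path. Keys: `label`; `inputs` (list of
#'   `{path, label}`); `scale` ("kd", a file, or a named vector); `aliases`;
#'   `units` (list of selectors `{label, chains, ranges}`; omit chains and
#'   ranges for the whole complex); `subsets` (any of `interface`, `ligands`,
#'   `ss`, `zones`, `sheets`, `custom` with their parameters); `kGrid`
#'   (`{kMax, step}`); `levittExponent` (8 or 9); `sigmaDivisor`;
#'   `outputDir`; `seed`. Unknown keys are rejected.
#' @return A [FodReport-class].
#' @export
runAnalysis <- function(config) {
  config <- validateConfig(config)
  sc <- resolveScale(config$scale)
  aliases <- if (is.null(config$aliases) || identical(config$aliases, "default"))
    defaultAliases() else unlist(config$aliases)
  decisions <- character()
  log <- function(line) decisions <<- c(decisions, line)
  log(sprintf("scale: %s", sc$name))
  log(sprintf("sigma rule: extent/%g, floor 1 A; field centre: mean", config$sigmaDivisor))
  log(sprintf("levitt cutoff 9 A, final exponent %d, self term excluded",
              config$levittExponent))
  log(sprintf("K grid: 0..%g step %g, ties toward smaller K",
              config$kGrid$kMax, config$kGrid$step))

  results <- list()
  profiles <- list()
  hashes <- character()
  for (inp in config$inputs) {
    stopifnot(!is.null(inp$path))
    ilabel <- inp$label %||% basename(inp$path)
    st <- assignScale(loadStructure(inp$path, aliases = aliases),
                      sc$scale, aliases)
    hashes[ilabel] <- unname(tools::md5sum(inp$path))
    for (sel in config$units) {
      unit <- tryCatch(selectorUnit(st, sel), error = function(e) {
        log(sprintf("%s / %s: ERROR %s", ilabel, sel$label %||% "unit",
                    conditionMessage(e)))
        NULL
      })
      if (is.null(unit)) next
      unit@label <- paste(ilabel, unit@label, sep = ":")
      t <- theoreticalProfile(unit, fitField(unit, config$sigmaDivisor))
      o <- observedProfile(unit, exponent = config$levittExponent)
      whole <- fodStats(profileValues(t), profileValues(o), unit@label,
                        "whole", config$kGrid$kMax, config$kGrid$step)
      results[[length(results) + 1L]] <- whole
      log(sprintf("%s / whole: N=%d RD=%.3f K=%.1f", unit@label, whole@n,
                  whole@rd, whole@kOpt))
      profiles[[unit@label]] <- profileTable(unit, t, o, k = whole@kOpt)
      results <- c(results, subsetResults(st, unit, t, o, config$subsets,
                                          config$kGrid, log))
    }
  }
  if (!length(results)) stop("run produced no results (see decision log)")
  res <- resultsTable(results)
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res, file.path(config$outputDir, "results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (lb in names(profiles)) {
      utils::write.table(profiles[[lb]],
                         file.path(config$outputDir,
                                   paste0("profile_", gsub("[^A-Za-z0-9_.-]", "_", lb), ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  methods::new("FodReport", label = config$label, results = res,
               profiles = profiles, decisions = decisions, inputHash = hashes)
}

reportProfile <- function(report, unit) {
  if (!unit %in% names(report@profiles))
    stop("unknown unit label ", sQuote(unit), "; available: ",
         paste(names(report@profiles), collapse = ", "))
  report@profiles[[unit]]
}

#' Paired comparison of two runs over analogous segments
#'
#' Scores analogous residue ranges of two runs side by side: for each pair,
#' the fragment statistics (by renormalising the stored whole-unit T and O
#' profiles) plus the Pearson correlation of the observed-profile segments
#' (the longer segment linearly resampled to the shorter).
#'
#' @param a,b two [FodReport-class] objects.
#' @param pairs data.frame with columns unitA, startA, endA, unitB, startB,
#'   endB (author residue numbering, inclusive) and optionally chainA/chainB
#'   (default: first chain of the stored profile).
#' @param kMax,step K grid for the fragment optimisation.
#' @return data.frame: one row per pair with N, RD, K and RD_Kopt for each
#'   side and the O-segment correlation.
#' @export
compareRuns <- function(a, b, pairs, kMax = 10, step = 0.1) {
  pairs <- as.data.frame(pairs)
  need <- c("unitA", "startA", "endA", "unitB", "startB", "endB")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns ", paste(need, collapse = ", "))
  one <- function(report, unit, chain, start, end, tag) {
    pf <- reportProfile(report, unit)
    if (is.null(chain) || is.na(chain)) chain <- pf$chain_id[1]
    mask <- pf$sequential_index[pf$chain_id == chain &
                                pf$seq_id >= start & pf$seq_id <= end]
    if (length(mask) < 2L)
      stop("dangling range in pair ", tag, ": ", unit, " ", chain, " ",
           start, "-", end)
    r <- fragmentStatus(pf$T, pf$O, mask,
                        subsetLabel = sprintf("%d-%d", start, end),
                        unitLabel = unit, kMax = kMax, step = step)
    list(r = r, o = pf$O[mask])
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    ra <- one(a, p$unitA, p$chainA, p$startA, p$endA, i)
    rb <- one(b, p$unitB, p$chainB, p$startB, p$endB, i)
    data.frame(fragmentA = ra$r@subsetLabel, nA = ra$r@n, rdA = ra$r@rd,
               kA = ra$r@kOpt, rdKoptA = ra$r@rdKopt,
               fragmentB = rb$r@subsetLabel, nB = rb$r@n, rdB = rb$r@rd,
               kB = rb$r@kOpt, rdKoptB = rb$r@rdKopt,
               correlationO = profileCorrelation(ra$o, rb$o),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Plot the T/O/M profiles of a unit
#'
#' Line plot of the theoretical (navy), observed (pink) and membrane-modified
#' (turquoise, at the run's optimal K) distributions against the sequential
#' residue index. With `report2`/`unit2`, overlays the second run's M profile
#' for paired comparisons; the legend carries the K values.
#'
#' @param report a [FodReport-class].
#' @param unit unit label within the report.
#' @param report2,unit2 optional second run/unit to overlay (M profiles).
#' @param file optional output path (written via [ggplot2::ggsave()]).
#' @return A ggplot object, invisibly when writing to file.
#' @export
plotProfiles <- function(report, unit, report2 = NULL, unit2 = NULL,
                         file = NULL) {
  pf <- reportProfile(report, unit)
  hasM <- "M" %in% names(pf)
  long <- data.frame(
    sequential_index = rep(pf$sequential_index, if (hasM) 3 else 2),
    value = c(pf$T, pf$O, if (hasM) pf$M),
    series = rep(c("T", "O", if (hasM) sprintf("M (K=%s)", mLabel(report, unit))),
                 each = nrow(pf)))
  if (!is.null(report2)) {
    unit2 <- unit2 %||% unit
    pf2 <- reportProfile(report2, unit2)
    if (!"M" %in% names(pf2)) stop("second report has no M profile for ", unit2)
    long <- rbind(long, data.frame(
      sequential_index = pf2$sequential_index, value = pf2$M,
      series = sprintf("M' (K=%s)", mLabel(report2, unit2))))
  }
  cols <- c(T = "navy", O = "deeppink3")
  mser <- setdiff(unique(long$series), c("T", "O"))
  cols <- c(cols, stats::setNames(c("turquoise3", "darkorange")[seq_along(mser)],
                                  mser))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$sequential_index,
                                          y = .data$value,
                                          colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = cols, name = NULL) +
    ggplot2::labs(x = "sequential residue index",
                  y = "normalised hydrophobicity", title = unit) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 9, height = 4)
    return(invisible(p))
  }
  p
}

mLabel <- function(report, unit) {
  r <- report@results
  k <- r$k_opt[r$unit_label == unit & r$subset_label == "whole"]
  if (length(k)) sprintf("%.1f", k[1]) else "?"
}
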