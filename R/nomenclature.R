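#' Lipid shorthand nomenclature
#'
#' Lipid species are named by a headgroup-class code followed by either a sum
#' composition ("PC 34:2", total acyl carbons : total double-bond equivalents)
#' or an underscore-separated list of acyl chains ("TG 18:3_18:3_18:2").
#' Oxidized acyl chains carry a ";O" suffix counting oxygens beyond the
#' carbonyl oxygen ("DGDG 16:0_18:3;O"). Sterol lipids use the sterol name:
#' "sitosterol 18:2" is a sterol ester (SE), "Sitosterol-Glc" a sterol
#' glycoside (SG), and "Sitosterol-Glc 16:0" an acylated sterol glycoside
#' (ASG).
#'
#' @name nomenclature
NULL

.sterol_names <- c("sitosterol", "stigmasterol", "campesterol")

# cached taxonomy, reset when a user supplies an override file
.tax_env <- new.env(parent = emptyenv())

#' Headgroup-class taxonomy
#'
#' Returns the taxonomy of lipid headgroup classes: short code, number of
#' acyl positions (NA where the chain structure is unknown, e.g. GSL),
#' subcellular compartment category, and whether the class is one of the
#' plastidic or extra-plastidic membrane diacyl classes.
#'
#' @param path Optional path to a user-supplied taxonomy TSV with columns
#'   `name`, `n_acyl_positions`, `compartment`, `is_membrane_diacyl`.
#'   Defaults to the taxonomy shipped with the package.
#' @return A tibble with one row per headgroup class.
#' @export
#' @examples
#' headgroup_classes()
headgroup_classes <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.tax_env$default)) return(.tax_env$default)
    path <- system.file("extdata", "headgroup_classes.tsv",
                        package = "lipidremodel", mustWork = TRUE)
    tax <- .read_taxonomy(path)
    .tax_env$default <- tax
    return(tax)
  }
  .read_taxonomy(path)
}

.read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  required <- c("name", "n_acyl_positions", "compartment", "is_membrane_diacyl")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("taxonomy file lacks column(s): ", paste(missing, collapse = ", "))
  }
  df$n_acyl_positions <- as.integer(df$n_acyl_positions)
  df$is_membrane_diacyl <- as.logical(df$is_membrane_diacyl)
  bad <- df$is_membrane_diacyl & !is.na(df$n_acyl_positions) &
    df$n_acyl_positions != 2L
  if (any(bad)) {
    stop("membrane-diacyl classes must have 2 acyl positions: ",
         paste(df$name[bad], collapse = ", "))
  }
  tibble::as_tibble(df)
}

.class_info <- function(class_name) {
  tax <- headgroup_classes()
  i <- match(class_name, tax$name)
  if (is.na(i)) return(NULL)
  as.list(tax[i, ])
}

#' Construct an acyl chain
#'
#' @param carbons Integer number of acyl carbons (>= 1).
#' @param double_bonds Integer number of C-C double-bond equivalents (>= 0).
#' @param extra_oxygens Integer number of oxygens beyond the carbonyl
#'   oxygen (>= 0); `1` denotes an oxidized chain such as `18:3;O`.
#' @return An object of class `acyl_chain`.
#' @export
#' @examples
#' acyl_chain(18, 3)
#' acyl_chain(18, 4, extra_oxygens = 1)  # e.g. the OPDA chain 18:4;O
acyl_chain <- function(carbons, double_bonds, extra_oxygens = 0L) {
  carbons <- as.integer(carbons)
  double_bonds <- as.integer(double_bonds)
  extra_oxygens <- as.integer(extra_oxygens)
  if (is.na(carbons) || carbons < 1L) stop("carbons must be >= 1")
  if (is.na(double_bonds) || double_bonds < 0L) stop("double_bonds must be >= 0")
  if (is.na(extra_oxygens) || extra_oxygens < 0L) stop("extra_oxygens must be >= 0")
  if (double_bonds > carbons %/% 2L) {
    stop("double_bonds (", double_bonds, ") exceeds floor(carbons / 2) for a ",
         carbons, "-carbon chain")
  }
  structure(
    list(carbons = carbons, double_bonds = double_bonds,
         extra_oxygens = extra_oxygens),
    class = "acyl_chain"
  )
}

#' @export
format.acyl_chain <- function(x, ...) {
  out <- paste0(x$carbons, ":", x$double_bonds)
  if (x$extra_oxygens == 1L) out <- paste0(out, ";O")
  else if (x$extra_oxygens > 1L) out <- paste0(out, ";O", x$extra_oxygens)
  out
}

#' @export
print.acyl_chain <- function(x, ...) {
  cat("<acyl_chain>", format(x), "\n")
  invisible(x)
}

# "18:3", "18:3;O", "18:4;O2" -> acyl_chain; NULL on malformed input
.parse_chain <- function(token) {
  m <- regmatches(token,
                  regexec("^([0-9]+):([0-9]+)(;O([0-9]*))?$", token))[[1]]
  if (length(m) == 0) return(NULL)
  extra <- 0L
  if (nzchar(m[4])) extra <- if (nzchar(m[5])) as.integer(m[5]) else 1L
  acyl_chain(as.integer(m[2]), as.integer(m[3]), extra)
}

#' Parse a lipid species shorthand name
#'
#' Accepts headgroup classes with sum compositions ("DGDG 36:6"), resolved
#' acyl-chain lists ("TG 18:3_18:3_18:2", "DGDG 16:0_18:3;O"), and sterol
#' species ("sitosterol 18:2" for SE, "Sitosterol-Glc" for SG,
#' "Sitosterol-Glc 16:0" for ASG; sterol names matched case-insensitively).
#' A species is acyl-resolved when its individual chains are determined:
#' underscore-separated names, and sum compositions of classes with a single
#' acyl position.
#'
#' @param name Species name in shorthand nomenclature.
#' @return An object of class `lipid_species` with fields `headgroup`,
#'   `sterol_moiety`, `chains` (list of [acyl_chain()] or `NULL`),
#'   `total_carbons`, `total_double_bonds`, `total_extra_oxygens`,
#'   `acyl_resolved`.
#' @seealso [format_species()], [count_acyl_occurrences()], [contains_chain()]
#' @export
#' @examples
#' parse_species("DGDG 36:6")
#' parse_species("TG 18:3_18:3_18:2")
#' parse_species("DGDG 16:0_18:3;O")
#' parse_species("sitosterol 18:2")
parse_species <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name)) {
    stop("species name must be a single non-empty string")
  }
  name <- trimws(name)
  parts <- strsplit(name, " +")[[1]]
  head_token <- parts[1]
  rest <- if (length(parts) > 1) paste(parts[-1], collapse = " ") else ""

  # sterol routes: "sitosterol 18:2" (SE), "Sitosterol-Glc" (SG),
  # "Sitosterol-Glc 16:0" (ASG)
  lower <- tolower(head_token)
  if (grepl("-glc$", lower)) {
    moiety <- sub("-glc$", "", lower)
    if (!moiety %in% .sterol_names) {
      stop("unknown sterol moiety in '", head_token, "'")
    }
    if (rest == "") {
      return(.new_species("SG", moiety, chains = list(), resolved = TRUE))
    }
    chain <- .parse_chain(rest)
    if (is.null(chain)) stop("malformed acyl composition '", rest, "' in '", name, "'")
    return(.new_species("ASG", moiety, chains = list(chain), resolved = TRUE))
  }
  if (lower %in% .sterol_names) {
    if (rest == "") stop("sterol ester '", name, "' lacks an acyl chain")
    chain <- .parse_chain(rest)
    if (is.null(chain)) stop("malformed acyl composition '", rest, "' in '", name, "'")
    return(.new_species("SE", lower, chains = list(chain), resolved = TRUE))
  }

  info <- .class_info(head_token)
  if (is.null(info)) {
    stop("unknown headgroup class '", head_token, "' in '", name, "'")
  }
  if (rest == "") stop("species '", name, "' lacks an acyl composition")
  n_pos <- info$n_acyl_positions

  if (grepl("_", rest)) {
    tokens <- strsplit(rest, "_", fixed = TRUE)[[1]]
    chains <- lapply(tokens, .parse_chain)
    bad <- vapply(chains, is.null, logical(1))
    if (any(bad)) {
      stop("malformed acyl chain '", tokens[which(bad)[1]], "' in '", name, "'")
    }
    if (is.na(n_pos)) {
      stop("class '", head_token,
           "' has unknown chain structure; acyl-resolved names are not supported")
    }
    if (length(chains) != n_pos) {
      stop("species '", name, "' lists ", length(chains), " chains but class '",
           head_token, "' has ", n_pos, " acyl position(s)")
    }
    return(.new_species(head_token, NULL, chains = chains, resolved = TRUE))
  }

  chain <- .parse_chain(rest)
  if (is.null(chain)) {
    stop("malformed acyl composition '", rest, "' in '", name, "'")
  }
  if (!is.na(n_pos) && n_pos == 1L) {
    # single acyl position: the sum composition IS the chain
    return(.new_species(head_token, NULL, chains = list(chain), resolved = TRUE))
  }
  .new_species(head_token, NULL, chains = NULL, resolved = FALSE,
               totals = chain)
}

.new_species <- function(class_name, moiety, chains, resolved, totals = NULL) {
  info <- .class_info(class_name)
  if (is.null(info)) stop("unknown headgroup class '", class_name, "'")
  if (!is.null(chains)) {
    tc <- sum(vapply(chains, function(ch) ch$carbons, integer(1)), 0L)
    td <- sum(vapply(chains, function(ch) ch$double_bonds, integer(1)), 0L)
    to <- sum(vapply(chains, function(ch) ch$extra_oxygens, integer(1)), 0L)
    if (!is.na(info$n_acyl_positions) && length(chains) != info$n_acyl_positions) {
      stop("class '", class_name, "' has ", info$n_acyl_positions,
           " acyl position(s), not ", length(chains))
    }
  } else {
    tc <- totals$carbons
    td <- totals$double_bonds
    to <- totals$extra_oxygens
  }
  structure(
    list(
      headgroup = info,
      sterol_moiety = moiety,
      chains = chains,
      total_carbons = as.integer(tc),
      total_double_bonds = as.integer(td),
      total_extra_oxygens = as.integer(to),
      acyl_resolved = isTRUE(resolved)
    ),
    class = "lipid_species"
  )
}

#' Format a lipid species to its canonical shorthand name
#'
#' Round-trips with [parse_species()]: `parse_species(format_species(s))` is
#' structurally equal to `s`.
#'
#' @param species A `lipid_species` object.
#' @return The canonical shorthand name.
#' @export
#' @examples
#' format_species(parse_species("TG 18:3_18:3_18:2"))
format_species <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  cls <- species$headgroup$name
  if (cls == "SE") {
    return(paste(species$sterol_moiety, format(species$chains[[1]])))
  }
  if (cls == "SG") {
    return(paste0(.cap(species$sterol_moiety), "-Glc"))
  }
  if (cls == "ASG") {
    return(paste(paste0(.cap(species$sterol_moiety), "-Glc"),
                 format(species$chains[[1]])))
  }
  if (species$acyl_resolved) {
    n_pos <- species$headgroup$n_acyl_positions
    if (!is.na(n_pos) && n_pos == 1L) {
      return(paste(cls, format(species$chains[[1]])))
    }
    return(paste(cls, paste(vapply(species$chains, format, character(1)),
                            collapse = "_")))
  }
  comp <- paste0(species$total_carbons, ":", species$total_double_bonds)
  if (species$total_extra_oxygens == 1L) comp <- paste0(comp, ";O")
  else if (species$total_extra_oxygens > 1L) {
    comp <- paste0(comp, ";O", species$total_extra_oxygens)
  }
  paste(cls, comp)
}

.cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

#' @export
format.lipid_species <- function(x, ...) format_species(x)

#' @export
print.lipid_species <- function(x, ...) {
  cat("<lipid_species>", format_species(x), "\n")
  cat("  class:", x$headgroup$name,
      paste0("(", x$headgroup$compartment, ")"),
      " resolved:", x$acyl_resolved, "\n")
  invisible(x)
}

#' Count acyl-chain occurrences in a resolved species
#'
#' Counts each distinct acyl chain with multiplicity. Oxidized chains (extra
#' oxygens > 0) are distinct from their unoxidized forms. Species whose acyl
#' composition is ambiguous (sum compositions on multi-position classes)
#' raise an error; chain-level statistics use only unambiguous species.
#'
#' @param species An acyl-resolved `lipid_species`.
#' @return A named integer vector; names are chain shorthand ("18:3",
#'   "18:3;O"), values are occurrence counts.
#' @export
#' @examples
#' count_acyl_occurrences(parse_species("TG 18:3_18:3_18:2"))
count_acyl_occurrences <- function(species) {
  stopifnot(inherits(species, "lipid_species"))
  if (!species$acyl_resolved) {
    stop("species '", format_species(species),
         "' is unresolved: its fatty acyl composition is ambiguous")
  }
  keys <- vapply(species$chains, format, character(1))
  tab <- table(keys)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Test whether a species contains a given acyl chain
#'
#' For acyl-resolved species the chains are inspected directly. For
#' unresolved diacyl species an optional user-supplied lookup can map sum
#' compositions to chain pairs (e.g. "36:6" -> di-18:3); without it,
#' unresolved species raise an error rather than guessing.
#'
#' @param species A `lipid_species`.
#' @param chain An [acyl_chain()] or chain shorthand string ("18:3").
#' @param infer Optional named list mapping sum-composition strings
#'   ("36:6") to character vectors of chain shorthands
#'   (`list("36:6" = c("18:3", "18:3"))`), used only for unresolved species
#'   of 2-position classes.
#' @return `TRUE` if the chain occurs at least once.
#' @export
#' @examples
#' contains_chain(parse_species("TG 18:3_18:3_18:2"), "18:3")
#' contains_chain(parse_species("DGDG 36:6"), "18:3",
#'                infer = list("36:6" = c("18:3", "18:3")))
contains_chain <- function(species, chain, infer = NULL) {
  stopifnot(inherits(species, "lipid_species"))
  key <- if (inherits(chain, "acyl_chain")) format(chain) else as.character(chain)
  if (species$acyl_resolved) {
    return(key %in% vapply(species$chains, format, character(1)))
  }
  n_pos <- species$headgroup$n_acyl_positions
  if (!is.null(infer) && !is.na(n_pos) && n_pos == 2L) {
    comp <- paste0(species$total_carbons, ":", species$total_double_bonds)
    if (comp %in% names(infer)) {
      return(key %in% infer[[comp]])
    }
  }
  stop("species '", format_species(species),
       "' is unresolved and no chain inference covers it")
}
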