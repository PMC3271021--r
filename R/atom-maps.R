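#' Parse carbon atom-transition definitions
#'
#' The plain-text format has one mapping per line,
#' `rxn_id: met[abc] + met2[de] -> met3[abde] + co2[c]`, where the letters
#' name carbon positions (position 1 first). Every product carbon must come
#' from exactly one substrate carbon and every substrate carbon must land
#' in exactly one product (a bijection), so each mapping can also be
#' reversed for bidirectional (exchange) flux. A reaction may have several
#' mapping lines; they are treated as equally weighted variants, the
#' standard device for molecules with rotational symmetry (succinate,
#' fumarate).
#'
#' Lines starting with `#` and blank lines are ignored.
#'
#' @param path file to read, or `NULL` when `text` is given.
#' @param text character vector of mapping lines (overrides `path`).
#' @return an `atom_map` object: list of transitions, each with `rxn`,
#'   `subs`/`prods` (lists of `met`, `carbons`), and `weight`
#'   (1/number-of-variants); plus `n_carbon`, the carbon count per
#'   metabolite.
#' @export
parse_atom_maps <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- readLines(path)
  text <- trimws(text)
  text <- text[nzchar(text) & !startsWith(text, "#")]
  parse_side <- function(s) {
    terms <- strsplit(s, "\\+")[[1]]
    lapply(terms, function(term) {
      m <- regmatches(term, regexec("^\\s*([A-Za-z0-9_]+)\\s*\\[([a-z]+)\\]\\s*$",
                                    term))[[1]]
      if (length(m) != 3) stop("cannot parse atom-map term: ", term)
      list(met = m[2], carbons = strsplit(m[3], "")[[1]])
    })
  }
  trans <- lapply(text, function(line) {
    m <- regmatches(line, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.+?)\\s*->\\s*(.+)$",
                                  line))[[1]]
    if (length(m) != 4) stop("cannot parse atom-map line: ", line)
    subs <- parse_side(m[3])
    prods <- parse_side(m[4])
    sub_letters <- unlist(lapply(subs, `[[`, "carbons"))
    prod_letters <- unlist(lapply(prods, `[[`, "carbons"))
    if (anyDuplicated(sub_letters))
      stop("duplicate substrate carbon label in: ", line)
    if (anyDuplicated(prod_letters))
      stop("duplicate product carbon label in: ", line)
    if (!setequal(sub_letters, prod_letters))
      stop("carbon not conserved (unmapped product or substrate carbon) in: ",
           line)
    list(rxn = m[2], subs = subs, prods = prods)
  })
  # equal weights across mapping variants of the same reaction
  ids <- vapply(trans, `[[`, "", "rxn")
  for (i in seq_along(trans)) trans[[i]]$weight <- 1 / sum(ids == ids[[i]])
  # per-metabolite carbon counts, checked for consistency
  n_carbon <- new.env(parent = emptyenv())
  for (tr in trans)
    for (side in c(tr$subs, tr$prods)) {
      nc <- length(side$carbons)
      prev <- n_carbon[[side$met]]
      if (is.null(prev)) n_carbon[[side$met]] <- nc
      else if (prev != nc)
        stop("inconsistent carbon count for ", side$met)
    }
  structure(list(transitions = trans,
                 n_carbon = unlist(as.list(n_carbon))),
            class = "atom_map")
}

#' @export
print.atom_map <- function(x, ...) {
  cat(sprintf("Atom map: %d mapping(s), %d reaction(s), %d metabolite(s)\n",
              length(x$transitions),
              length(unique(vapply(x$transitions, `[[`, "", "rxn"))),
              length(x$n_carbon)))
  invisible(x)
}

#' Write atom maps back to their text format
#'
#' @param am an `atom_map`.
#' @param path output file.
#' @export
write_atom_maps <- function(am, path) {
  fmt_side <- function(side)
    paste(vapply(side, function(s)
      sprintf("%s[%s]", s$met, paste(s$carbons, collapse = "")), ""),
      collapse = " + ")
  lines <- vapply(am$transitions, function(tr)
    sprintf("%s: %s -> %s", tr$rxn, fmt_side(tr$subs), fmt_side(tr$prods)),
    "")
  writeLines(lines, path)
  invisible(path)
}

# isotopomer state indexing: an n-carbon metabolite has 2^n states; carbon
# k contributes bit 2^(k-1), so state index = 1 + sum(bit_k * 2^(k-1)) and
# index 1 is the unlabeled molecule.
idv_index <- function(bits) 1L + sum(bits * 2L^(seq_along(bits) - 1L))

#' Isotopomer mapping matrix for one substrate-product pair
#'
#' The 0/1 operator transferring substrate isotopomer fractions to product
#' isotopomers: entry `[j, i] = 1` when substrate isotopomer `i` puts the
#' product carbons inherited from this substrate into the labeling state
#' `j` (carbons of the product that originate from other substrates of the
#' reaction are taken unlabeled, which makes every column sum to exactly
#' 1; multi-substrate reactions are composed exactly from the joint
#' substrate distribution inside the balance solver).
#'
#' @param at one transition from [parse_atom_maps()] (an element of
#'   `$transitions`).
#' @param substrate,product metabolite ids; default to the first substrate
#'   and first product of the transition.
#' @return a `2^n_prod` x `2^n_sub` 0/1 matrix.
#' @export
#' @examples
#' am <- parse_atom_maps(text = "PDH: pyr[abc] -> co2[a] + accoa[bc]")
#' imm <- build_imm(am$transitions[[1]], "pyr", "accoa")
#' dim(imm)           # 4 x 8
#' colSums(imm)       # all 1
build_imm <- function(at, substrate = at$subs[[1]]$met,
                      product = at$prods[[1]]$met) {
  sub <- Filter(function(s) s$met == substrate, at$subs)
  prod <- Filter(function(s) s$met == product, at$prods)
  if (!length(sub)) stop("substrate ", substrate, " not in transition")
  if (!length(prod)) stop("product ", product, " not in transition")
  sub <- sub[[1]]; prod <- prod[[1]]
  all_sub_letters <- unlist(lapply(at$subs, `[[`, "carbons"))
  unmapped <- setdiff(prod$carbons, all_sub_letters)
  if (length(unmapped))
    stop("unmapped product carbon(s): ", paste(unmapped, collapse = ", "))
  ns <- length(sub$carbons); np <- length(prod$carbons)
  imm <- matrix(0L, 2^np, 2^ns)
  for (i in seq_len(2^ns)) {
    bits_s <- as.integer(intToBits(i - 1L))[seq_len(ns)]
    bits_p <- integer(np)
    for (k in seq_len(np)) {
      pos <- match(prod$carbons[k], sub$carbons)
      if (!is.na(pos)) bits_p[k] <- bits_s[pos]
    }
    imm[idv_index(bits_p), i] <- 1L
  }
  imm
}

# Precompile an atom map against a model for the balance solver: for every
# transition (and its reverse, needed for exchange fluxes) and every
# product, a dense operator from the joint substrate space
# (kron over substrates, first substrate fastest) to the product space.
compile_atom_maps <- function(am) {
  compile_dir <- function(subs, prods, rxn, weight) {
    sub_mets <- vapply(subs, `[[`, "", "met")
    sub_nc <- vapply(subs, function(s) length(s$carbons), 1L)
    joint_dim <- prod(2^sub_nc)
    joint_letters <- unlist(lapply(subs, `[[`, "carbons"))
    ops <- lapply(prods, function(pr) {
      np <- length(pr$carbons)
      M <- matrix(0, 2^np, joint_dim)
      for (i in seq_len(joint_dim)) {
        bits_joint <- as.integer(intToBits(i - 1L))[seq_len(sum(sub_nc))]
        bits_p <- bits_joint[match(pr$carbons, joint_letters)]
        M[idv_index(bits_p), i] <- 1
      }
      list(met = pr$met, M = M)
    })
    list(rxn = rxn, weight = weight, sub_mets = sub_mets, ops = ops)
  }
  fwd <- lapply(am$transitions, function(tr)
    compile_dir(tr$subs, tr$prods, tr$rxn, tr$weight))
  rev <- lapply(am$transitions, function(tr)
    compile_dir(tr$prods, tr$subs, tr$rxn, tr$weight))
  list(fwd = fwd, rev = rev, n_carbon = am$n_carbon)
}

#' Carbon atom transitions of the toy central-carbon network
#'
#' Companion to [build_toy_model()]: carbon mappings for every
#' carbon-carrying reaction of the toy network, with two equally weighted
#' mapping variants for the symmetric intermediates succinate and fumarate
#' (rotational scrambling at SUCOAS, SDH and FUM). Decarboxylations follow
#' the canonical positions (pyruvate C1 lost at PDH, so a C3 label lands on
#' the acetyl-CoA methyl carbon).
#'
#' @return an `atom_map`.
#' @export
toy_atom_maps <- function() {
  parse_atom_maps(text = c(
    "LDH: lac[abc] -> pyr[abc]",
    "PDH: pyr[abc] -> co2[a] + accoa[bc]",
    "ACS: accoa[ab] -> ace[ab]",
    "CS: oaa[abcd] + accoa[ef] -> cit[dcbfea]",
    "ICDH: cit[abcdef] -> akg[abcde] + co2[f]",
    "AKGDH: akg[abcde] -> co2[a] + succoa[bcde]",
    "SUCOAS: succoa[abcd] -> suc[abcd]",
    "SUCOAS: succoa[abcd] -> suc[dcba]",
    "SDH: suc[abcd] -> fum[abcd]",
    "SDH: suc[abcd] -> fum[dcba]",
    "FUM: fum[abcd] -> mal[abcd]",
    "FUM: fum[abcd] -> mal[dcba]",
    "MDH: mal[abcd] -> oaa[abcd]",
    "ICL: cit[abcdef] -> glx[ab] + suc[cdef]",
    "MALS: glx[ab] + accoa[cd] -> mal[abdc]",
    "ME2: mal[abcd] -> pyr[abc] + co2[d]",
    "PYC: pyr[abc] + co2[d] -> oaa[abcd]",
    "GNG: oaa[abcd] -> g3p[abc] + co2[d]",
    "SERS: g3p[abc] -> ser[abc]",
    "GHMT: ser[abc] -> gly[ab] + c1[c]",
    "GLYCL: gly[ab] -> co2[a] + c1[b]",
    "C1OX: c1[a] -> co2[a]"
  ))
}

#' Amino-acid precursor map of the toy network
#'
#' Proteinogenic amino acids tracked by the labeling simulator, their
#' precursor metabolites and the biomass drain coefficients (mmol per g
#' DCW, equal to the precursor's stoichiometry in the toy biomass
#' reaction). The carbon backbone is inherited unchanged from the
#' precursor (Ala from pyruvate, Asp from oxaloacetate, Glu from
#' 2-oxoglutarate, Ser from serine, Gly from glycine).
#'
#' @return data frame with columns `aa`, `precursor`, `coeff`.
#' @export
toy_amino_acid_map <- function() {
  data.frame(
    aa = c("Ala", "Asp", "Glu", "Ser", "Gly"),
    precursor = c("pyr", "oaa", "akg", "ser", "gly"),
    coeff = c(2.5, 2.0, 2.2, 1.0, 1.2))
}
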