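# Morpheme inventories for pseudo-Latin binomials. Fixed lists: the
# generator's output distribution is part of the package's test conditions.
GENUS_PREFIXES <- c(
  "lacto", "strepto", "staphylo", "entero", "pepto", "actino", "myco",
  "fuso", "porphyro", "clostri", "bifido", "campylo", "helico", "neisseri",
  "prevo", "rumino", "veillo", "trepo", "aggregati", "seleno", "lepto",
  "acineto", "pseudo", "moraxo", "brady", "rhodo", "sphingo", "thermo",
  "methano", "chloro", "geo", "nitro", "sulfo", "xantho", "vibrio")
GENUS_STEMS <- c(
  "bacillus", "coccus", "bacter", "monas", "spira", "myces", "plasma",
  "nema", "sarcina", "philus", "genium", "spirillum", "ella", "torquis")
SPECIES_STEMS <- c(
  "alb", "aur", "gingiv", "mutan", "pylor", "fragil", "nucleat", "acn",
  "intermedi", "dentic", "salivari", "buccal", "haemolytic", "ferment",
  "vagin", "long", "brev", "parv", "mit", "casei", "plantar", "oral",
  "faecal", "sangui", "pneumo", "melanino", "durans", "lent", "rect")
SPECIES_ENDINGS <- c("is", "us", "um", "a", "ii", "ans", "ensis", "icum",
                     "osus", "atum", "ica", "ense")

# Filler (non-entity) vocabulary with fixed Penn POS templates, so generated
# corpora carry a POS column without any external tagger.
FILLER <- matrix(c(
  "the", "DT", "a", "DT", "an", "DT", "this", "DT", "these", "DT",
  "patients", "NNS", "samples", "NNS", "isolates", "NNS", "infection", "NN",
  "plaque", "NN", "disease", "NN", "biofilm", "NN", "mucosa", "NN",
  "abundance", "NN", "prevalence", "NN", "colonization", "NN", "lesions", "NNS",
  "cultures", "NNS", "subjects", "NNS", "saliva", "NN", "tissue", "NN",
  "was", "VBD", "were", "VBD", "is", "VBZ", "are", "VBP", "detected", "VBN",
  "isolated", "VBN", "observed", "VBN", "associated", "VBN", "increased", "VBN",
  "reduced", "VBN", "cultured", "VBN", "identified", "VBN", "showed", "VBD",
  "suggests", "VBZ", "in", "IN", "of", "IN", "with", "IN", "from", "IN",
  "among", "IN", "between", "IN", "during", "IN", "chronic", "JJ",
  "periodontal", "JJ", "subgingival", "JJ", "healthy", "JJ", "severe", "JJ",
  "significant", "JJ", "higher", "JJR", "and", "CC", "or", "CC", "but", "CC",
  "not", "RB", "frequently", "RB", "significantly", "RB", ",", ",", ";", ":"),
  ncol = 2, byrow = TRUE,
  dimnames = list(NULL, c("word", "pos")))

cap1 <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

random_genus <- function() {
  cap1(paste0(sample(GENUS_PREFIXES, 1L), sample(GENUS_STEMS, 1L)))
}

random_epithet <- function() {
  paste0(sample(SPECIES_STEMS, 1L), sample(SPECIES_ENDINGS, 1L))
}

#' Synthetic-corpus configuration
#'
#' Controls the generator that emulates tokenized abstract sentences:
#' multi-token bacterial binomials (pseudo-Latin, capitalized genus +
#' lowercase epithet) embedded in fixed-vocabulary non-entity context.
#'
#' @param n_genera number of genera in the lexicon.
#' @param n_species_per_genus species per genus.
#' @param n_sentences sentences to generate.
#' @param len_range inclusive range of sentence lengths (tokens).
#' @param entities_range inclusive range of entity mentions per sentence.
#' @param oov_entity_rate fraction of mentions drawn from outside the
#'   emitted lexicon (novel binomials; their dictionary feature is all `O`).
#' @param abbrev_rate fraction of mentions rendered with an abbreviated
#'   genus (`"P."`-style initial), which also defeats dictionary matching.
#' @param p_monomial,p_trinomial fractions of lexicon entries that are 1- or
#'   3-token names (the remainder are 2-token binomials).
#' @param seed RNG seed; (config, seed) fully determines the output.
#' @return validated list of class `synth_config`.
#' @export
synth_config <- function(n_genera = 20, n_species_per_genus = 4,
                         n_sentences = 100, len_range = c(8, 18),
                         entities_range = c(1, 3), oov_entity_rate = 0.3,
                         abbrev_rate = 0.1, p_monomial = 0, p_trinomial = 0,
                         seed = 1L) {
  cfg <- list(n_genera = n_genera, n_species_per_genus = n_species_per_genus,
              n_sentences = n_sentences, len_range = len_range,
              entities_range = entities_range,
              oov_entity_rate = oov_entity_rate, abbrev_rate = abbrev_rate,
              p_monomial = p_monomial, p_trinomial = p_trinomial,
              seed = as.integer(seed))
  rates <- c(oov_entity_rate, abbrev_rate, p_monomial, p_trinomial)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (p_monomial + p_trinomial > 1) stop("p_monomial + p_trinomial > 1")
  if (n_genera < 1 || n_species_per_genus < 1 || n_sentences < 1) {
    stop("counts must be >= 1")
  }
  if (length(len_range) != 2 || len_range[1] < 3 || diff(len_range) < 0) {
    stop("len_range must be an increasing pair with minimum >= 3")
  }
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic bacterial-name lexicon
#'
#' Draws `n_genera` unique pseudo-Latin genus names (capitalized morpheme
#' chains) and `n_species_per_genus` epithets each; entries are binomials by
#' default, with configurable 1- and 3-token fractions. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return list with `lexicon` (a [ner_lexicon()]), `names` (display
#'   surfaces, original capitalization) and `tokens` (list of token
#'   vectors).
#' @export
generate_lexicon <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  genera <- character(0)
  while (length(genera) < cfg$n_genera) {
    genera <- unique(c(genera, random_genus()))
  }
  genera <- genera[seq_len(cfg$n_genera)]
  tokens <- list()
  for (g in genera) {
    eps <- character(0)
    while (length(eps) < cfg$n_species_per_genus) {
      eps <- unique(c(eps, random_epithet()))
    }
    for (e in eps[seq_len(cfg$n_species_per_genus)]) {
      u <- stats::runif(1)
      tokens[[length(tokens) + 1L]] <-
        if (u < cfg$p_monomial) g
        else if (u < cfg$p_monomial + cfg$p_trinomial) c(g, e, random_epithet())
        else c(g, e)
    }
  }
  tokens <- unique(tokens)
  names <- vapply(tokens, paste, "", collapse = " ")
  list(lexicon = ner_lexicon(names), names = names, tokens = tokens)
}

#' Generate a synthetic tagged corpus
#'
#' Each sentence embeds 1+ bacterial mentions in filler context. A mention
#' is drawn from the lexicon, or (with probability `oov_entity_rate`) is a
#' novel binomial outside it; with probability `abbrev_rate` the genus is
#' rendered as an initial (`"P. gingivalis"` style). Gold tags are IOB2 over
#' `bacteria`; the POS column comes from fixed templates (genus/abbreviation
#' `NNP`, epithets `NN`, filler templates); the dictionary column is
#' computed by [bdmm_tag()] against the emitted lexicon, so in-lexicon
#' mentions carry their gold pattern and OOV/abbreviated ones read `O`.
#'
#' @param cfg a [synth_config()].
#' @param lex output of [generate_lexicon()] (regenerated from `cfg` if
#'   missing).
#' @return A [ner_corpus()]; attributes `n_mentions` and `n_oov` carry the
#'   generator's internal counters.
#' @export
generate_corpus <- function(cfg, lex = generate_lexicon(cfg)) {
  stopifnot(inherits(cfg, "synth_config"))
  if (lex$lexicon$n == 0L) stop("lexicon is empty")
  set.seed(cfg$seed + 1000003L)
  n_mentions <- 0L; n_oov <- 0L
  sentences <- vector("list", cfg$n_sentences)
  for (si in seq_len(cfg$n_sentences)) {
    L <- sample(cfg$len_range[1]:cfg$len_range[2], 1L)
    k <- sample(cfg$entities_range[1]:cfg$entities_range[2], 1L)
    mentions <- vector("list", k)
    for (j in seq_len(k)) {
      oov <- stats::runif(1) < cfg$oov_entity_rate
      toks <- if (oov) {
        repeat {
          cand <- c(random_genus(), random_epithet())
          if (!lex_has(lex$lexicon, lex_key(cand))) break
        }
        cand
      } else lex$tokens[[sample(length(lex$tokens), 1L)]]
      pos <- c("NNP", rep("NN", length(toks) - 1L))
      if (length(toks) > 1L && stats::runif(1) < cfg$abbrev_rate) {
        toks[1L] <- paste0(substr(toks[1L], 1L, 1L), ".")
      }
      n_mentions <- n_mentions + 1L
      if (oov) n_oov <- n_oov + 1L
      mentions[[j]] <- list(toks = toks, pos = pos,
                            tag = c("B-bacteria",
                                    rep("I-bacteria", length(toks) - 1L)))
    }
    n_fill <- max(L - sum(lengths(lapply(mentions, `[[`, "toks"))), k)
    fill_idx <- sample(nrow(FILLER), n_fill, replace = TRUE)
    # insert mentions at distinct gaps between fillers (no adjacent mentions)
    gaps <- sort(sample.int(n_fill, k))
    surf <- character(0); pos <- character(0); tag <- character(0)
    prev <- 0L
    for (j in seq_len(k)) {
      seg <- fill_idx[seq_len(gaps[j] - prev) + prev]
      surf <- c(surf, FILLER[seg, "word"], mentions[[j]]$toks)
      pos <- c(pos, FILLER[seg, "pos"], mentions[[j]]$pos)
      tag <- c(tag, rep("O", length(seg)), mentions[[j]]$tag)
      prev <- gaps[j]
    }
    if (prev < n_fill) {
      seg <- fill_idx[(prev + 1L):n_fill]
      surf <- c(surf, FILLER[seg, "word"])
      pos <- c(pos, FILLER[seg, "pos"])
      tag <- c(tag, rep("O", length(seg)))
    }
    dict <- bdmm_tag(surf, lex$lexicon)
    sentences[[si]] <- ner_sentence(surf, pos, dict, tag)
  }
  corpus <- ner_corpus(sentences,
                       tag_alphabet = c("O", "B-bacteria", "I-bacteria"))
  attr(corpus, "n_mentions") <- n_mentions
  attr(corpus, "n_oov") <- n_oov
  corpus
}

#' Corpus summary statistics
#'
#' @param corpus a [ner_corpus()].
#' @return list with `sentences`, `tokens`, `entities`, `entity_tokens`
#'   (entities decoded from the gold tag column).
#' @export
corpus_stats <- function(corpus) {
  stopifnot(inherits(corpus, "ner_corpus"))
  tokens <- 0L; entities <- 0L; etok <- 0L
  for (s in corpus$sentences) {
    tokens <- tokens + s$n
    if (s$n == 0L || anyNA(s$tag)) next
    sp <- tags_to_spans(s$tag)
    entities <- entities + nrow(sp)
    if (nrow(sp)) etok <- etok + sum(sp$end - sp$start + 1L)
  }
  list(sentences = length(corpus$sentences), tokens = tokens,
       entities = entities, entity_tokens = etok)
}
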