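---
title: "Two-phase core collection selection: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase core collection selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreselect)
```

## The problem

A genebank's *entire collection* of accessions is too large to phenotype,
regenerate, or even genotype deeply; breeders work instead with a *core
collection* — a small subset chosen to represent the genetic diversity of the
whole with minimal redundancy. `coreselect` builds such cores from a
markers-by-accessions matrix of categorical SNP genotype calls, targeting the
"representative" style of core in which each accession of the collection
should be echoed by a nearby entry and every marker's allele repertoire should
be retained.

All selection and most evaluation in this package treat genotype calls as
opaque categorical labels — the *genotype classes* of a marker (for a
biallelic SNP typically the two homozygotes and the heterozygote). No allele
decomposition, dosage model, or map information is needed except for the
modified Rogers distance, described below.

## Criteria

**Coverage.** For a core $C$,
$$\mathrm{CV}(C) = \frac{1}{m}\sum_{i=1}^{m} \frac{c_i(C)}{e_i},$$
where $e_i$ is the number of genotype classes of marker $i$ in the entire
collection and $c_i(C)$ the number of those classes present among the core's
non-missing calls at marker $i$. CV is monotone: adding an entry never lowers
it. Markers whose calls are all missing carry no class information and are
excluded from $m$ (they are reported by `build_class_table()`).

**Base-c Shannon diversity.** Coverage says nothing about evenness: a marker
with class counts 5/45/50 is fully covered by a core holding 1/1/8 of the
classes, yet a breeder screening for the rare class would prefer more copies
of it. Per marker we compute the Shannon index of the core's class
proportions with logarithm base $e_i$, so every marker scores in $[0, 1]$
with 1 meaning perfectly even proportions; the reported SH is the unweighted
mean over markers (unweighted because CV is also an unweighted mean, and one
scalar per core is wanted).

**Modified Rogers distance.** The mean pairwise distance among entries
measures how spread out the core is. For a pair of accessions each call is
decomposed into allele tokens (a two-character label such as `AA` or a
slash-separated label such as `0/1` gives two tokens; anything else is one
opaque token), dosages are 1 for a homozygote's allele and 0.5 for each
allele of a heterozygote, and
$$\mathrm{MR}(a,b) = \sqrt{\frac{1}{2\,m_{\text{used}}}
  \sum_i \sum_{\text{alleles}} (d_{a} - d_{b})^2},$$
over the $m_{\text{used}}$ markers where both accessions are called. This is
the standard normalized form bounded by 1; pairwise-complete handling of
missing data is our choice, made because no missing-data rule is standard.
Labels that do not decompose are treated as single-token alleles, so two
different such labels contribute the maximal squared difference.

**Rarity score.** With $p_{ij}$ the entire-collection proportion of class $j$
at marker $i$, the odds of drawing that class are
$\eta_{ij} = p_{ij}/(1-p_{ij})$. An accession's rarity score sums the inverse
odds of its own classes:
$$\mathrm{RS} = \sum_i \frac{1-p_{ij^*}}{p_{ij^*}},$$
$j^*$ being the class the accession carries at marker $i$; missing markers
contribute 0. An accession carrying a class seen in 5 of 100 samples earns
$(1-0.05)/0.05 = 19$ from that marker alone, so high-RS accessions are
exactly the rare-allele carriers. `make_worked_toy()` packages this 100-sample
example as an executable fixture.

## The two-phase algorithm

**Covering phase** (`select_covering()`). A deterministic greedy: at each
iteration the accession whose inclusion raises CV most joins the core, until
the user's `max_cv` is reached. Two operations accelerate the scan without
changing the result:

1. once a (marker, class) pair is covered, every cell holding that class is
   voided in a working copy of the grid — a candidate's gain is then simply
   the weighted count of its non-voided cells, with weight $1/(m\,e_i)$ per
   cell of marker $i$;
2. markers whose classes are all covered are dropped from the working grid.

`naive_greedy_reference()` implements the same rule with a full CV
recomputation for every candidate at every iteration; the test suite asserts
exact entry-sequence equality between the two on dozens of seeded random
panels, which is the correctness argument for the accelerations.

**Thickening phase** (`thicken()`). Core size grows steeply in the last
percent of CV, and those late entries are chosen for coverage bookkeeping,
not diversity. Given user thresholds `min_cv` $\le$ `max_cv`, let $n_{\min}$
and $n_{\max}$ be the core sizes at which the covering run attained them. The
thickened core keeps the first $n_{\min}$ covering entries and appends the
$n_{\max} - n_{\min}$ accessions with the highest rarity scores from
everything outside that truncated core. The result has the same size as the
covering core, coverage at least `min_cv`, and provably a mean rarity score
at least that of the covering core (the appended entries are the RS maxima of
a pool that contains the entries they replace). `select_two_phase()` returns
both cores with full evaluation reports, so users can pick either.

## Parameters that matter

* `min_cv`, `max_cv` — proportions in (0, 1] (the CLI also accepts
  percentages). Defaults 0.98 and 0.99: the widely used operating point where
  coverage is essentially complete but the last percent is expensive.
  Lowering `min_cv` at fixed `max_cv` admits more rare-allele carriers at a
  small CV cost.
* `gain` — `"weighted"` (default) uses the exact CV increment. The
  `"unweighted"` variant scores candidates by the raw count of their
  uncovered cells, a cheaper rule used by earlier coverage-greedy tools; the
  two coincide only when all markers have equal class numbers, which is why
  weighted is the default.
* `first` — the first entry is chosen by the same maximal-gain rule as every
  other iteration (`"greedy"`, default). `"min-missing"` reproduces the
  convention of picking the accession with the fewest missing calls first.
  Note that on a complete-data panel every accession has the same first-round
  weighted gain, so the first pick then falls to the tie rule.

## Numerical and degenerate-input choices

* **Tie-breaking.** Equal gains (within $10^{-12}$) and equal rarity scores
  are resolved by fewer missing calls in the input, then by input column
  order. Selection is therefore fully deterministic across runs and
  platforms; a different but equally valid tie rule can change the entry
  list without changing the attained CV.
* **Threshold comparisons** use a $10^{-12}$ slack so that coverage values
  sitting exactly on a percent boundary are not missed to floating-point
  rounding.
* **Monomorphic markers** ($e_i = 1$): the base-1 logarithm is undefined, so
  per-marker SH is set to 1 — the single class trivially has even
  proportions, consistent with the base-$e_i$ normalization contract.
  `shannon_index(..., monomorphic = "exclude")` instead drops such markers
  from the mean.
* **$0 \log 0 = 0$** throughout SH; a polymorphic marker at which the core
  has no non-missing call scores SH 0 (no diversity observed).
* **log(RS)** reported for a core is the natural logarithm of the mean
  per-entry RS. Base and aggregation are a convention; the per-entry scores
  are exposed in the evaluation report so any alternative is recomputable.
* **Rarest-class ties** are broken by lexicographically first label, keeping
  the per-marker diagnostics deterministic.
* **Empty cores** have CV 0 by definition; Shannon, MR and the evaluation
  report require at least one (for MR, two) entries. Singleton cores are
  reported with MR flagged unavailable rather than an error.
* **Unattainable `max_cv`** cannot strand the covering loop: a positive gain
  exists whenever CV < 1, so covering stops only at `max_cv`, at CV = 1, or
  with every accession selected (full collection, flagged with a warning).

## The synthetic panel generator

`simulate_panel()` draws biallelic markers independently: minor-allele
frequency $q$ from a configurable spectrum (default uniform on
$[0.05, 0.5]$), then genotypes under Hardy–Weinberg proportions with an
inbreeding coefficient $F$,
$P(\mathrm{AA}) = p^2 + Fpq$, $P(\mathrm{AB}) = 2pq(1-F)$,
$P(\mathrm{BB}) = q^2 + Fpq$. The default $F = 0.9$ emulates the
heterozygote-poor panels of selfing crops such as wheat, which yields the
2-to-3-classes-per-marker structure the selection algorithm actually faces;
the default 2% per-cell missingness is typical of array calls. Planted rare
carriers are written after missingness and removed from all non-carriers, so
planted class frequencies are exact. Each marker uses a sub-stream derived
from the global seed, so enlarging a panel never perturbs the markers already
drawn.

The generator deliberately omits linkage disequilibrium, population
structure, and pedigree: markers are exchangeable and independent. Passing
tests on such panels therefore validate the combinatorics and arithmetic of
selection and evaluation — greedy/oracle equivalence, metric identities,
rare-carrier enrichment — but say nothing about how core composition reacts
to real LD blocks or stratified collections, where the greedy entries will
co-vary with structure.

For the planted-rare-carrier test campaigns the panels use a fixed MAF of 0.3
and $F = 0.5$ with 100 accessions: every background class count then sits far
above 1, so a planted singleton (frequency 0.01, rarity term 99) is the
unique rarest class and dominates the spread of baseline rarity scores —
the regime in which rare-carrier recovery is a well-posed expectation.

Test and acceptance problem sizes — property campaigns on roughly 20 x 15
panels, end-to-end runs on 2000 markers x 300 accessions — were chosen as the
smallest scales at which every behavior of interest (multi-class markers,
missing data, threshold crossings, rare-carrier competition) is exercised;
the algorithms are the same at any scale.

## Known limitations

* CV treats all markers equally; a marker with many classes is harder to
  cover but not worth more.
* The MR missing-data rule (pairwise-complete markers) can make distances
  between sparsely called accessions noisy.
* Thickening ranks accessions by total RS, so an accession rich in moderately
  rare classes can outrank the carrier of one extremely rare class at very
  large marker counts.
* No imputation, and no PLINK/HapMap readers; inputs are delimited genotype
  tables or VCF.
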