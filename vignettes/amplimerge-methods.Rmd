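---
title: "Quality-aware assembly of paired-end amplicon reads: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-aware assembly of paired-end amplicon reads: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplimerge)
```

# The problem

Short amplicons — here sized on a 16S rRNA V3 region of about 135 bases —
are sequenced from both ends, producing a forward and a reverse read whose
3' ends cover the same template positions. Merging the two reads into one
full-length sequence requires (i) deciding how far they overlap, (ii)
reconciling disagreeing and uncalled bases in the overlap, and (iii)
deciding which products to trust. All three decisions can exploit the
per-base quality scores the base caller already provides; discarding any
pair with an imperfect overlap wastes exactly the pairs the mate read
could repair.

# Probability model

## Per-base error rates

A quality character with ASCII value $A$ encodes the miscall probability
$\epsilon = 10^{-(A-\mathrm{offset})/10}$, offset 33 (CASAVA $\ge$ 1.8) or
64 (earlier pipelines). `read_fastq_pairs()` detects the encoding from the
first records (any character below ASCII 59 forces offset 33; a sample
entirely at or above 64 with something above 74 forces offset 64; anything
else defaults to 33 with a warning) and an explicit flag overrides it.
Every $\epsilon$ is floored at $10^{-4.1}$ — phred 41, the platform's best
assigned score — so no base is ever treated as certainly correct and no
per-base probability ever reaches exactly 1 from the agree rule.

## Aligned-pair probabilities

Assuming a uniform prior over nucleotides and that sequencing errors are
equiprobable over the other three bases, two aligned observed bases $X, Y$
are truly equal with probability

$$\Pr[\hat X=\hat Y \mid X=Y] = (1-\epsilon_X)(1-\epsilon_Y)
  + \tfrac{\epsilon_X\epsilon_Y}{3},$$
$$\Pr[\hat X=\hat Y \mid X\ne Y] = \tfrac13(1-\epsilon_X)\epsilon_Y
  + \tfrac13(1-\epsilon_Y)\epsilon_X + \tfrac29\epsilon_X\epsilon_Y,$$

and $\tfrac14$ when either base is uncalled (N), irrespective of the
partner's quality — base callers attach the lowest score to N, so its
quality carries no information. Both expressions recover the uniform prior
$\tfrac14$ at $\epsilon_X=\epsilon_Y=0.75$, the random-call limit; the test
suite asserts this identity together with symmetry, bounds, and
monotonicity along the equal-$\epsilon$ diagonal.

Pipelines sometimes *mask* the unreliable end of a read, overwriting
trailing quality scores with the lowest value (phred 2, `#`/`B`).
`detect_masked_tail()` flags the maximal trailing run of phred $\le 2$;
interior low-quality runs are not masked, since masking is strictly a
tail phenomenon. For an aligned pair with at least one masked base:
agreeing bases with exactly one masked side take the unmasked side's own
correctness probability $1-\epsilon$ (the only probability attached to a
single base in this model); disagreeing or doubly-masked pairs take
$\tfrac14$.

# The three-step assembly

## Primer location

If a primer sequence $P$ is supplied, the assembler scans offsets
$x = 0,\dots,5$ and scores each window by
$\sum_i \log \Pr[\hat S_{i+x} = P_i]$, treating primer bases as carrying
the platform's best error rate $\epsilon_P = 10^{-4.1}$: a read base inside
the primer symbol's IUPAC set contributes the agree term, outside it the
disagree term, and an uncalled read base $\tfrac14$. The first offset whose
per-base *geometric mean* agreement reaches 0.75 qualifies; the window and
everything before it are clipped from the final assembly. Two choices here
were genuinely open:

* **Qualification rule.** "The primer aligns" needs an operational
  definition. A geometric-mean threshold (default 0.75) is
  length-independent and tolerates a single low-quality mismatch in a
  17-mer while rejecting windows with a confident mismatch, whose
  geometric mean collapses (one disagree term among 16 agree terms pulls
  the mean below 0.7 for typical qualities).
* **Search bound.** Offsets beyond 5 are not searched: in Illumina
  amplicon layouts the primer begins at or within a few bases of the read
  start, and bounding the scan keeps "first qualifying offset" semantics
  cheap and deterministic.

Degenerate IUPAC codes are exact-match sets — no partial credit by
degeneracy. Pairs whose specified primer is not found are rejected with
reason `primer-missing`: without the primer position the biological
sequence start is unknown. A primer given as an integer instead strips a
fixed number of bases, for pre-trimmed or unsequenced-primer data. The
$\epsilon_P$ value deserves a note: the error rate of a primer base is
described as the platform's best score, which corresponds to
$10^{-4.1}$; the package uses that value throughout.

## Overlap selection

The reverse read is reverse-complemented, with its error probabilities and
masked flags reversed in lockstep. Every candidate overlap length
$c \in [\texttt{min\_overlap}, \min(|F|,|R|)]$ is scored:

$$\log\Pr[F,R\mid c] = (f+r)\log\tfrac14 \;+\;
  \sum_{i=1}^{c}\log p_i,$$

where $f = |F|-c$ and $r = |R|-c$ count unpaired positions and $p_i$ is
the agree/disagree/uncalled probability of aligned pair $i$ evaluated at a
*fixed* error rate (default $\epsilon = 0.01$, a nominal platform average;
the argmax is insensitive to its exact value, so it is deliberately not
estimated per run). Scanning is exhaustive — no seeding heuristics, and no
gapped alignment, since indels are rare on this platform. Numerical
choices:

* **Log space.** Scores are sums of up to $|F|+|R|$ logs of values
  $\le 1$; products would underflow doubles on long reads.
* **Exact tie handling.** Each candidate's score is assembled as
  $n_{eq}\log p_e + n_{ne}\log p_u + n_N\log\tfrac14 + (f+r)\log\tfrac14$
  from integer counts (in a small compiled kernel), so candidates with
  identical composition have bit-identical scores and ties are exact, not
  tolerance-based.
* **Ties go to larger $c$** — the shorter assembly, i.e. the hypothesis
  explaining more observed data as overlap, and a deterministic rule.
* **Closed upper bound.** $c = \min(|F|,|R|)$ is allowed, so fully
  overlapping short templates (where reads run through the opposite
  primer) remain assemblable.
* **Masked flags do not enter the scan**; the fixed-$\epsilon$ likelihood
  already ignores per-base quality, and masking matters only for
  reconstruction. This is an interpretation, made explicitly.

The scan runs over the entire reads, including primer regions, because a
long overlap may legitimately extend into them. Only an empty candidate
range (reads shorter than `min_overlap`) rejects a pair at this stage,
with reason `no-overlap`; quality problems are left to the downstream
filter.

## Reconstruction, scoring, validation

Position by position over the $f$ forward-only, $c$ overlapping, and $r$
reverse-only positions: unpaired positions copy the available strand with
$p = 1-\epsilon$; agreeing called pairs keep the base at the agree
probability; disagreeing called pairs keep the base with the smaller
$\epsilon$ at the disagree probability — on an exact quality tie the
forward base, a deterministic convention for a case the model cannot
decide (forward cycles are sequenced earlier and tend to be cleaner);
pairs with an uncalled base keep the called base at $\tfrac14$ (both
uncalled yields N at $\tfrac14$); pairs with a masked base use the
masked-pair rule above. Mismatches resolved and uncalled bases rescued are
counted per assembly.

Primer regions are clipped *before* the quality statistic is computed, so
the reported score describes exactly the reported sequence; the geometric
mean $\exp(\mathrm{mean}(\log p_i))$ then runs over all retained
positions, including the $\tfrac14$ contributions of N-rescued positions
— they are genuine uncertainty about the reported base and excluding them
would flatter the score. The geometric mean compensates for variable
assembly lengths and is bounded below by the minimum per-base probability,
so a sequence whose every base clears a threshold clears it overall.

Validation applies rules in a fixed order — quality below `min_quality`,
too short, too long, contains N — recording only the first failing reason;
named user hooks (predicates on sequence and probabilities) run after the
built-ins, filling the role of a plug-in validation stage for checks such
as secondary-structure or conserved-region screens, which the package
itself does not implement. The default threshold is 0.6, the relaxed
operating point; 0.9 is the conservative, documented alternative — on
error-free data under real quality masks assemblies score above 0.9, so
demanding more than 0.9 demands better underlying reads than perfectly
correct data provides.

# The simulator and what it does (not) show

`simulate_pairs()` lays out `fwd_primer + template + revcomp(rev_primer)`,
takes the forward read as the prefix and the reverse read as the reverse
complement of the suffix (108-base reads over a 135-base template by
default, giving a true overlap of 81), and emulates four features of real
data, chosen once as the study conditions:

* **Quality decline**: per-base phred falls linearly 40 → 15 along the
  read — the canonical Illumina within-read trend. Because the two reads
  decline in opposite template directions, each read's weak tail lands on
  the other's strong region, which is precisely the regime in which
  quality-aware correction pays off.
* **Masked tails**: 20% of reads get a phred-2 tail of uniform length
  1–15, reproducing CASAVA-style masking.
* **Substitutions** are drawn per base at the quality-implied rate
  $10^{-\mathrm{phred}/10}$ (after masking — a masked base really is
  unreliable), uniform over the other three nucleotides, matching the
  model's own error assumption.
* **Uncalled bases**: bases with phred $\le 15$ become N with probability
  0.02, and every N carries phred 2, the masking value, since base callers
  attach their lowest score to N. The rate and cutoff are this package's
  choices where no established figure exists; they put Ns where they occur
  in practice, in the low-quality tail.

`transplant_masks()` reproduces the error-free validation design: exact
template bases under supplied quality strings, so any assembly error is
attributable to the algorithm rather than the reads. `evaluate_assemblies()`
classifies each accepted assembly by comparing output and inputs to the
truth in template coordinates: *error-free*, *errors retained* (output
errors equal input errors), *errors reduced*, and *errors introduced* (an
output error where both reads were correct). Because every output base is
copied from one of the input reads, the introduced category can only be
populated by a mis-chosen overlap shifting the alignment — which is why it
is the critical indicator, and why length-mismatched assemblies are
assigned to it.

Passing tests on these simulations show that the implementation realises
the model and corrects errors in the intended direction. They do not show
performance on real runs: the synthetic profile has no platform-specific
correlations between neighbouring qualities, no sequence-context error
biases, no chimeras or abundance structure, and the masked tails are
synthetic rather than harvested from a real flow cell. Quantitative claims
tied to real quality masks are therefore out of reach of this test bed.

# Problem sizes and reproducibility

The validation experiments use 10,000 simulated pairs per condition (1,000
for the overlap-oracle and primer-recovery checks), sizes at which the
binomial uncertainty on the reported percentages is well below the margins
being asserted; the whole suite runs in well under a minute. All
randomness flows from a single integer seed (`withr::with_seed`), so
every experiment is bit-reproducible; repeated runs of the file-level
pipeline are asserted byte-identical.

# Known limitations

* Pairs are processed in memory as tibbles rather than streamed; at
  survey scale (millions of pairs) a chunked driver around the same
  functions would be needed.
* No gapped overlap alignment: an indel in either read shifts the
  alignment and will typically be rejected by the quality filter rather
  than repaired.
* Negative-overhang layouts (reads reading through the opposite primer
  *past* each other) are representable only through primer clipping of a
  full overlap.
* The fixed-$\epsilon$ overlap scan treats all positions as equally
  reliable; a per-base-quality scan would differ mainly where masked
  tails dominate the overlap, a regime the quality filter already
  discards.
* FASTA/FASTQ output only; demultiplexing, adapter trimming, chimera
  detection, and downstream clustering belong to other tools.
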