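# zmlentropy

Shannon entropy and entropy-rate estimation for symbolic sequences —
text, DNA, protein, or any token stream — in the undersampled regime,
using analytic Zipf–Mandelbrot–Li (ZML) rank models and coincidence
counting.

## The problem

The plug-in estimator
H&#770; = −Σᵢ p&#770;(xᵢ) log₂ p&#770;(xᵢ)
needs a good frequency estimate for *every* symbol, including the rare
ones, so it converges slowly and with a systematic negative bias when the
sample size is not much larger than the alphabet.  Many natural sequences,
however, are approximately Zipfian: their whole rank-probability profile
is pinned down by a single quantity, the alphabet size *M*.  That turns
entropy estimation into a one-parameter problem that can be solved from
the statistics of a *single frequent symbol*.

## The method

1. **Analytic rank models.**  The ZML law gives the probability of the
   rank-*r* symbol as P(r; M) = γ′ / (r + β)^α with closed-form
   parameters α = log(M+1)/log M and β = M/(M+1), normalized over ranks
   1..M.  Two linguistically constrained variants shrink the underlying
   word space: `czml1` forbids adjacent repeated letters (branching
   M−1, so α̃ = log(M+1)/log(M−1)), and `czml2` reduces the continuation
   branching to a free B ≤ M−1 (α̃ = log(M+1)/log B).

2. **Coincidence counting.**  The distance between consecutive
   occurrences of a symbol (counting the first occurrence as draw 1;
   in `abcdabc` the distance for `a` is 5) has mean 1 + 1/P(r; M) for
   i.i.d. draws.  Measuring the mean distance D̄ of the rank-1 symbol and
   inverting the calibrated forward model M&#770; = G(θ; D̄) recovers the
   alphabet size; plugging M&#770; back into the ZML law yields the whole
   distribution and hence its entropy.  The inversion is available in
   closed form (the package default) or as a power-law / polynomial curve
   fitted to a seeded simulation ensemble, the form M = a·D^b + c being
   invertible as D = ((M−c)/a)^(1/b).

3. **Sample-complexity planning.**  The Dvoretzky–Kiefer–Wolfowitz
   inequality bounds the samples needed to pin a ranked probability to
   within its rank gap Δᵣ = P(r) − P(r+1):
   N_r = ⌈8 P(r)/Δᵣ² · ln(2/(1−ζ′))⌉.  The ratio of the rank-M to the
   rank-1 requirement, λ_f(M), quantifies the advantage of rank-1
   estimation — two to four orders of magnitude for M in 20–40.

4. **Entropy rate.**  Block entropies H_N over overlapping n-grams give
   conditional rates h_N = H_N − H_{N−1}, reported at the largest block
   size each estimator can support reliably.

## Worked example

```r
library(zmlentropy)

m <- zml_model(30)            # ZML law at alphabet size 30
model_entropy(m)              # 4.382801 bits -- the true entropy

x <- sample_iid_sequence(m, 1e6, seed = 42)
estimate_entropy_model(x)
#> <entropy_estimate> H = 4.3831 bits  (perplexity 20.867)
#>   method=zml_coincidence  M_hat=30.428  rank=1  n=1000000
```

The estimate agrees with the true value to three decimals using only the
repeat distances of the most frequent symbol.  At small samples the
advantage over plug-in estimation is in the bias: averaging 1500 seeded
trials of length 1000,

```r
run_convergence_experiment(M = 30, Ns_grid = 1e3, Nv = 1500,
                           methods = c("model", "plugin"), seed = 2)
#>   method   Ns  mean      sd trials
#> 1  model 1000 4.383 0.23942   1500
#> 2 plugin 1000 4.362 0.03985   1500
```

the model-based mean sits on the true 4.3828 bits while the plug-in mean
is biased low by 0.021 bits.  The planner explains why so few samples
suffice:

```r
required_samples(m, 1, 0.95)
#> <sample_bound> family=zml M=30 rank=1
#>   p_r=0.16880 Delta_r=0.05732 eps_r=0.02866 zeta'=0.950 -> N_r = 1517
convergence_factor(30)   # 1641.3 -- rank-1 needs ~1600x fewer samples
```

Entropy rates of a corpus use the same estimators on n-gram streams:

```r
txt <- preprocess_text(readLines("corpus.txt"))
entropy_rate(txt, N_max = 4, method = "model")    # bits per character
```

A command-line wrapper over these functions is installed at
`inst/cli/zml-entropy` (subcommands `estimate`, `entropy-rate`,
`calibrate`, `plan`, `simulate`, `experiment`, `model-pmf`).

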