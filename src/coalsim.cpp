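#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Multispecies-coalescent simulator with instantaneous admixture pulses.
//
// The species tree is passed as parent pointers over its 2S-1 nodes
// (0-based; tips 0..S-1 at time 0; root parent = -1) plus node times in
// coalescent units (2N generations). One haploid lineage is sampled per
// species and traced rootward. Each species-tree branch is a population;
// within a population, lineage pairs coalesce at rate 1 per pair per
// unit time. At a speciation node's time the child populations merge; at
// a pulse, each lineage currently in the recipient population switches
// to the donor population with the stated probability (the backward-time
// reading of forward admixture). A single insertion is then dropped on a
// genealogy branch chosen proportional to its duration; the locus is
// present exactly in the tips below that branch. Homoplasy-free by
// construction: no losses, no parallel gains.
//
// All randomness comes from R's RNG, so set.seed() in R makes runs
// bit-reproducible.

struct Event {
    double time;
    int type;   // 0 = population merge (speciation node), 1 = pulse
    int a;      // merge: species node id; pulse: recipient population
    int b;      // pulse: donor population
    double prob;
};

// [[Rcpp::export]]
List sim_msc_cpp(int n_loci, int S,
                 IntegerVector sp_parent, NumericVector sp_time,
                 NumericVector ev_time, IntegerVector ev_type,
                 IntegerVector ev_a, IntegerVector ev_b, NumericVector ev_prob,
                 bool condition, int min_present, int min_absent,
                 bool return_trees, double max_tries) {
    if (S < 2 || S > 62) stop("between 2 and 62 taxa supported");
    const int n_ev = ev_time.size();
    const int n_gnodes = 2 * S - 1;

    IntegerMatrix patterns(S, n_loci);
    IntegerMatrix gparents;
    NumericMatrix gtimes;
    if (return_trees) {
        gparents = IntegerMatrix(n_gnodes, n_loci);
        gtimes = NumericMatrix(n_gnodes, n_loci);
    }

    std::vector<int> lin(S), pop(S);
    std::vector<int> gpar(n_gnodes);
    std::vector<double> gt(n_gnodes);
    std::vector<uint64_t> mask(n_gnodes);
    std::vector<double> blen(n_gnodes);

    double tries = 0;
    for (int locus = 0; locus < n_loci; ++locus) {
        bool accepted = false;
        while (!accepted) {
            if (++tries > max_tries)
                stop("rejection sampling exceeded max_tries; conditioning may be degenerate");
            // init one lineage per tip
            int nact = S;
            for (int i = 0; i < S; ++i) {
                lin[i] = i;
                pop[i] = i;
                gpar[i] = -1;
                gt[i] = 0.0;
                mask[i] = (uint64_t)1 << i;
            }
            int nextnode = S;
            double t = 0.0;
            int iev = 0;
            while (nact > 1) {
                double tend = (iev < n_ev) ? ev_time[iev] : R_PosInf;
                // coalescence phase on [t, tend)
                for (;;) {
                    if (nact <= 1) break;
                    // per-population pair rates
                    double totrate = 0.0;
                    for (int i = 0; i < nact; ++i) {
                        int k = 0;
                        for (int j = 0; j < nact; ++j)
                            if (pop[j] == pop[i]) ++k;
                        totrate += (double)(k - 1);   // counts each pair twice/2*2
                    }
                    totrate *= 0.5;
                    if (totrate <= 0.0) { t = tend; break; }
                    double dt = R::exp_rand() / totrate;
                    if (t + dt >= tend) { t = tend; break; }
                    t += dt;
                    // choose an unordered pair uniformly among within-pop pairs
                    double u = unif_rand() * totrate * 2.0;
                    int ia = -1, ib = -1;
                    double acc = 0.0;
                    for (int i = 0; i < nact && ia < 0; ++i)
                        for (int j = 0; j < nact; ++j) {
                            if (j == i || pop[j] != pop[i]) continue;
                            acc += 1.0;
                            if (acc >= u) { ia = i; ib = j; break; }
                        }
                    if (ia < 0) {   // numerical guard: take any within-pop pair
                        for (int i = 0; i < nact && ia < 0; ++i)
                            for (int j = i + 1; j < nact; ++j)
                                if (pop[j] == pop[i]) { ia = i; ib = j; break; }
                    }
                    if (ia > ib) { int tmp = ia; ia = ib; ib = tmp; }
                    int nn = nextnode++;
                    gpar[lin[ia]] = nn;
                    gpar[lin[ib]] = nn;
                    gt[nn] = t;
                    gpar[nn] = -1;
                    mask[nn] = mask[lin[ia]] | mask[lin[ib]];
                    lin[ia] = nn;               // pop unchanged
                    lin[ib] = lin[nact - 1];
                    pop[ib] = pop[nact - 1];
                    --nact;
                }
                if (iev < n_ev) {
                    t = ev_time[iev];
                    if (ev_type[iev] == 0) {
                        int v = ev_a[iev];
                        for (int i = 0; i < nact; ++i)
                            if (sp_parent[pop[i]] == v) pop[i] = v;
                    } else {
                        for (int i = 0; i < nact; ++i)
                            if (pop[i] == ev_a[iev] && unif_rand() < ev_prob[iev])
                                pop[i] = ev_b[iev];
                    }
                    ++iev;
                } else if (nact > 1) {
                    stop("internal error: lineages stranded in disjoint populations");
                }
            }
            // insertion placement: branch of node v has duration gt[gpar[v]] - gt[v]
            double total = 0.0;
            for (int v = 0; v < n_gnodes - 1; ++v) {
                blen[v] = gt[gpar[v]] - gt[v];
                total += blen[v];
            }
            double r = unif_rand() * total;
            int chosen = n_gnodes - 2;
            double cum = 0.0;
            for (int v = 0; v < n_gnodes - 1; ++v) {
                cum += blen[v];
                if (r < cum) { chosen = v; break; }
            }
            uint64_t pat = mask[chosen];
            int np = 0;
            for (int i = 0; i < S; ++i) if ((pat >> i) & 1) ++np;
            accepted = !condition || (np >= min_present && (S - np) >= min_absent);
            if (accepted) {
                for (int i = 0; i < S; ++i)
                    patterns(i, locus) = (int)((pat >> i) & 1);
                if (return_trees) {
                    for (int v = 0; v < n_gnodes; ++v) {
                        gparents(v, locus) = gpar[v];
                        gtimes(v, locus) = gt[v];
                    }
                }
            }
        }
    }
    List out = List::create(_["patterns"] = patterns, _["tries"] = tries);
    if (return_trees) {
        out["gparents"] = gparents;
        out["gtimes"] = gtimes;
    }
    return out;
}
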