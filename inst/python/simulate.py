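"""Coalescent simulation helper.

Reads a demography scenario (JSON) plus a simulation configuration (JSON) and
writes one EIGENSTRAT .geno/.snp/.ind triplet per replicate. Invoked by the R
package; not intended as a user-facing tool.

Scenario schema (all times in generations before present, sizes are diploid
effective sizes):
  populations: [{name, size, samples, label}]
  splits:      [{time, derived: [names], ancestral}]          # new ancestor
  merges:      [{time, derived, into}]                        # lineage joins
  admixtures:  [{time, derived, ancestral: [a, b], proportion}]  # a's share
  pulses:      [{time, donor, recipient, proportion}]         # forward d->r
  migrations:  [{donor, recipient, rate, start, end}]         # forward, cont.

Config schema:
  chromosomes: [{chrom, length_bp}]
  mutation_rate, recombination_rate, samples_per_population (default used when
  a population has samples == null), ploidy fixed at 2 (each diploid is a
  pair of simulated haploid genomes).
"""

import argparse
import json
import sys

import msprime
import numpy as np
import tskit


def build_demography(sc):
    dem = msprime.Demography()
    for p in sc["populations"]:
        dem.add_population(name=p["name"], initial_size=p["size"])
    for ev in sc.get("admixtures", []):
        prop = float(ev["proportion"])
        prop = min(max(prop, 0.0), 1.0)
        if prop <= 0.0:
            dem.add_mass_migration(time=ev["time"], source=ev["derived"],
                                   dest=ev["ancestral"][1], proportion=1.0)
        elif prop >= 1.0:
            dem.add_mass_migration(time=ev["time"], source=ev["derived"],
                                   dest=ev["ancestral"][0], proportion=1.0)
        else:
            dem.add_admixture(time=ev["time"], derived=ev["derived"],
                              ancestral=list(ev["ancestral"]),
                              proportions=[prop, 1.0 - prop])
    for ev in sc.get("splits", []):
        dem.add_population_split(time=ev["time"], derived=list(ev["derived"]),
                                 ancestral=ev["ancestral"])
    for ev in sc.get("merges", []):
        dem.add_mass_migration(time=ev["time"], source=ev["derived"],
                               dest=ev["into"], proportion=1.0)
    for ev in sc.get("pulses", []):
        # forward-time donor -> recipient: backwards, recipient lineages move
        dem.add_mass_migration(time=ev["time"], source=ev["recipient"],
                               dest=ev["donor"], proportion=ev["proportion"])
    for mg in sc.get("migrations", []):
        start = float(mg.get("start", 0.0))
        end = float(mg["end"])
        rate = float(mg["rate"])
        # forward donor -> recipient at rate m: backwards recipient -> donor
        if start > 0:
            dem.add_migration_rate_change(time=start, rate=rate,
                                          source=mg["recipient"], dest=mg["donor"])
        else:
            dem.set_migration_rate(source=mg["recipient"], dest=mg["donor"],
                                   rate=rate)
        dem.add_migration_rate_change(time=end, rate=0.0,
                                      source=mg["recipient"], dest=mg["donor"])
    dem.sort_events()
    return dem


def extract_biallelic(mts, rate_m, chrom_id):
    """Diploid derived-allele counts plus SNP metadata for one tree sequence.

    Keeps strictly biallelic sites (ancestral observed, one derived allele)
    with strictly increasing integer positions.
    """
    if mts.num_sites == 0:
        return None
    G = mts.genotype_matrix()  # sites x haploids, allele indices
    keep = np.where((G.min(axis=1) == 0) & (G.max(axis=1) == 1))[0]
    if keep.size == 0:
        return None
    tab = mts.tables
    anc_states = tskit.unpack_strings(tab.sites.ancestral_state,
                                      tab.sites.ancestral_state_offset)
    der_states = tskit.unpack_strings(tab.mutations.derived_state,
                                      tab.mutations.derived_state_offset)
    first_mut = np.full(mts.num_sites, len(der_states), dtype=np.int64)
    np.minimum.at(first_mut, tab.mutations.site,
                  np.arange(len(der_states), dtype=np.int64))
    pos = tab.sites.position[keep].astype(np.int64) + 1
    inc = pos > np.concatenate(([0], np.maximum.accumulate(pos)[:-1]))
    keep = keep[inc]
    pos = pos[inc]
    Gk = G[keep]
    dip = (Gk[:, 0::2] + Gk[:, 1::2]).astype(np.int8)
    snp = [(f"rs{chrom_id}_{i + 1}", chrom_id, int(p) * rate_m, int(p),
            anc_states[j], der_states[first_mut[j]])
           for i, (j, p) in enumerate(zip(keep, pos))]
    return dip, snp


def run_batch(sc, cfg, dem, samples, group_seed, n):
    """Simulate a group of replicates, chromosome-major to amortize setup."""
    geno = [[] for _ in range(n)]
    snps = [[] for _ in range(n)]
    rate_m = cfg["recombination_rate"]
    for ci, chrom in enumerate(cfg["chromosomes"]):
        L = float(chrom["length_bp"])
        a_seed = (group_seed + 1000003 * (ci + 1)) % (2**31 - 2) + 1
        reps = msprime.sim_ancestry(
            samples=samples, demography=dem, sequence_length=L,
            recombination_rate=rate_m, random_seed=a_seed,
            num_replicates=n)
        for r, ts in enumerate(reps):
            m_seed = (a_seed + 500000003 + 7919 * r) % (2**31 - 2) + 1
            mts = msprime.sim_mutations(ts, rate=cfg["mutation_rate"],
                                        random_seed=m_seed)
            out = extract_biallelic(mts, rate_m, chrom["chrom"])
            if out is not None:
                geno[r].append(out[0])
                snps[r].append(out[1])
    return geno, snps


def write_replicate(dip_list, snp_list, sampled, out_prefix):
    if dip_list:
        dip = np.vstack(dip_list)
    else:
        n_ind = sum(k for (_, _, k) in sampled)
        dip = np.zeros((0, n_ind), dtype=np.int8)
        sys.stderr.write("warning: empty variant set\n")

    # EIGENSTRAT convention on disk: count of the reference allele
    disk = (2 - dip).astype(np.int8) + 48  # ASCII digits
    nl = np.full((disk.shape[0], 1), 10, dtype=np.int8)
    with open(out_prefix + ".geno", "wb") as fh:
        fh.write(np.hstack([disk, nl]).tobytes())

    with open(out_prefix + ".snp", "w") as fh:
        for rows in snp_list:
            for (sid, ch, gp, pp, ref, alt) in rows:
                fh.write(f"{sid}\t{ch}\t{gp:.10g}\t{pp}\t{ref}\t{alt}\n")

    with open(out_prefix + ".ind", "w") as fh:
        for (name, label, k) in sampled:
            for i in range(k):
                fh.write(f"{label}_{i + 1}\tU\t{label}\n")
    return dip.shape[0]


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--scenario", required=True)
    ap.add_argument("--config", required=True)
    ap.add_argument("--replicates", type=int, default=1)
    ap.add_argument("--seed", type=int, required=True)
    ap.add_argument("--out-prefix", required=True)
    ap.add_argument("--group-size", type=int, default=24)
    args = ap.parse_args()

    with open(args.scenario) as fh:
        sc = json.load(fh)
    with open(args.config) as fh:
        cfg = json.load(fh)

    dem = build_demography(sc)
    default_n = int(cfg.get("samples_per_population", 10))
    sampled = [(p["name"], p.get("label", p["name"]),
                int(p["samples"]) if p.get("samples") is not None else default_n)
               for p in sc["populations"] if p.get("samples", 0) != 0]
    sampled = [(nm, lb, k) for (nm, lb, k) in sampled if k > 0]
    samples = {nm: k for (nm, _, k) in sampled}

    reps = list(range(1, args.replicates + 1))
    for lo in range(0, len(reps), args.group_size):
        group = reps[lo:lo + args.group_size]
        # one seed per group: replicate data are deterministic given the
        # master seed and the (fixed) group size
        group_seed = (args.seed + 104729 * (lo // args.group_size)) % (2**31 - 2) + 1
        if args.replicates == 1:
            prefixes = [args.out_prefix]
        else:
            prefixes = [f"{args.out_prefix}_{r:03d}" for r in group]
        geno, snps = run_batch(sc, cfg, dem, samples, group_seed, len(group))
        for i, prefix in enumerate(prefixes):
            n = write_replicate(geno[i], snps[i], sampled, prefix)
            print(f"{prefix}\t{n}")


if __name__ == "__main__":
    main()
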