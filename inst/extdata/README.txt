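Place the ubiquitin crystal structure here as 1UBQ.pdb (from the Protein Data
Bank) to activate the crystal-distance checks in the test suite. The file is
not redistributed with the package.
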