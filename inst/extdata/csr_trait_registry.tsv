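pathway_name	class	trait	provenance
Biosynthesis of type II polyketide backbone	C	Biosynthesis of type II polyketide backbone	treatment-table
Biosynthesis of type II polyketide products	C	Biosynthesis of type II polyketide products	treatment-table
Clavulanic acid biosynthesis	C	Clavulanic acid biosynthesis	treatment-table
Carbapenem biosynthesis	C	Carbapenem biosynthesis	treatment-table
Biosynthesis of siderophore group nonribosomal peptides	C	Biosynthesis of siderophore group nonribosomal peptides	treatment-table
Acarbose and validamycin biosynthesis	C	Acarbose and validamycin biosynthesis	treatment-table
Polyketide sugar unit biosynthesis	C	Polyketide sugar unit biosynthesis	treatment-table
Staurosporine biosynthesis	C	Staurosporine biosynthesis	treatment-table
Biofilm formation	C	Biofilm formation	criteria-reconstructed
ABC transporters	conditional_CS	ABC transporters	treatment-table
Porphyrin and chlorophyll metabolism	S	Porphyrin and chlorophyll metabolism	treatment-table
Proteasome	S	Proteasome	treatment-table
Ascorbate and aldarate metabolism	S	Ascorbate and aldarate metabolism	treatment-table
Mismatch repair	S	Mismatch repair	treatment-table
Thiamine metabolism	S	Thiamine metabolism	treatment-table
Carbon metabolism	R	Carbon metabolism	treatment-table
TCA cycle	R	Carbon metabolism	treatment-table
Biosynthesis of amino acids	R	Biosynthesis of amino acids	treatment-table
Carbon-fixation pathways in prokaryotes	R	Carbon-fixation pathways in prokaryotes	treatment-table
Oxidative phosphorylation	R	Oxidative phosphorylation	treatment-table
2-Oxocarboxylic acid metabolism	R	2-Oxocarboxylic acid metabolism	treatment-table
Aminoacyl-tRNA biosynthesis	R	Aminoacyl-tRNA biosynthesis	treatment-table
Pyrimidine metabolism	R	Pyrimidine metabolism	treatment-table
Ribosome	R	Ribosome	treatment-table
One carbon pool by folate	R	One carbon pool by folate	treatment-table
Bacterial chemotaxis	foraging	Bacterial chemotaxis	criteria-reconstructed
Flagellar assembly	foraging	Flagellar assembly	criteria-reconstructed
Two-component system	foraging	Two-component system	criteria-reconstructed
Phosphotransferase system (PTS)	foraging	Phosphotransferase system (PTS)	criteria-reconstructed
Bacterial secretion system	foraging	Bacterial secretion system	criteria-reconstructed
Quorum sensing	foraging	Quorum sensing	criteria-reconstructed
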