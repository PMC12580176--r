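tool	entry	reason
AllerCatPro 2.0	SPV-I	misclassified
AllerCatPro 2.0	SPV-II	misclassified
AlgPred 2.0	Pan h 9.0101	misclassified
AlgPred 2.0	Pan h 11.01	misclassified
AlgPred 2.0	Sal s 9.01	misclassified
AlgPred 2.0	Onc m 1.0101	nonstandard
AlgPred 2.0	Onc m 1.0201	nonstandard
pLM4Alg-640	Lat c 6.0101	misclassified
pLM4Alg-640	Lat c 6.0201	misclassified
pLM4Alg-640	Sal s 6.0101	misclassified
pLM4Alg-640	Sal s 6.0102	misclassified
pLM4Alg-640	Sal s 6.0201	misclassified
pLM4Alg-640	Sal s 6.0202	misclassified
pLM4Alg-640	BAB55663.1	misclassified
pLM4Alg-640	Pan h 10.01	misclassified
AllergenFP v.1.0	Pan h 3.0101	misclassified
AllergenFP v.1.0	Sal s 3.0101	misclassified
AllergenFP v.1.0	Pan h 7.01	misclassified
AllergenFP v.1.0	Sal s 7.01	misclassified
AllergenFP v.1.0	Sal s 8.01	misclassified
AllergenFP v.1.0	Pan h 11.01	misclassified
AllergenFP v.1.0	Pan h 13.0101	misclassified
AllergenFP v.1.0	Onc m 1.0101	nonstandard
AllergenFP v.1.0	Onc m 1.0201	nonstandard
AllerTOP v.2.0	Pan h 3.0101	misclassified
AllerTOP v.2.0	Sal s 3.0101	misclassified
AllerTOP v.2.0	Pan h 7.01	misclassified
AllerTOP v.2.0	Sal s 7.01	misclassified
AllerTOP v.2.0	Sal s 8.01	misclassified
AllerTOP v.2.0	Pan h 11.01	misclassified
AllerTOP v.2.0	Pan h 13.0101	misclassified
AllerTOP v.2.0	Pan h 9.0101	misclassified
AllerTOP v.2.0	Sal s 9.01	misclassified
AllerTOP v.2.0	Pan h 8.01	misclassified
AllerTOP v.2.0	Pan h 10.01	misclassified
AllerTOP v.2.0	Onc m 1.0101	nonstandard
AllerTOP v.2.0	Onc m 1.0201	nonstandard
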