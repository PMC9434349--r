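diseaseId	diseaseName	icdCodes	dsm5Category	mergeGroup
BD01	Acute transient psychotic disorder	F23;F23.9	Schizophrenia Spectrum Disorder and other psychotic disorders	
BD02	Attention-Deficit/Hyperactivity Disorder	F90;F90.9	Neurodevelopmental disorders	
BD03	Attention-Deficit/Hyperactivity Disorder, combined type	F90.2	Neurodevelopmental disorders	
BD04	Autism Spectrum Disorders	F84.0	Neurodevelopmental disorders	
BD05	Bipolar Disorder	F31;F31.9	Bipolar and related disorders	
BD06	Bipolar II Disorder	F31.81	Bipolar and related disorders	
BD07	Catatonia, Organic	F06.1	Occurs in the context of disorders from different disease categories	
BD08	Catatonia	F06.1	Occurs in the context of disorders from different disease categories	
BD09	Cyclothymic Disorder	F34.0	Bipolar and related disorders	
BD10	Delusional disorder	F22.0	Schizophrenia Spectrum Disorder and other psychotic disorders	
BD11	Epilepsy	G40;G40.9;G40.909		
BD12	Hyperkinetic conduct disorder	F90.1	Neurodevelopmental disorders	
BD13	Incipient Schizophrenia	F21	Schizophrenia Spectrum Disorder and other psychotic disorders/Personality Disorders	
BD14	Involutional paraphrenia	F22	Schizophrenia Spectrum Disorder and other psychotic disorders	
BD15	Intellectual Disability (Mental deficiency)	F79	Neurodevelopmental disorders	intellectual-disability
BD16	Intellectual Disability (Mental handicap)	F79	Neurodevelopmental disorders	intellectual-disability
BD17	Intellectual Disability (Mental Retardation)	F70-F79.9	Neurodevelopmental disorders	intellectual-disability
BD18	Intellectual Disability (Mental Retardation, F79)	F79	Neurodevelopmental disorders	intellectual-disability
BD19	Mild Intellectual Disability	F70	Neurodevelopmental disorders	
BD20	Moderate Intellectual Disability	F71	Neurodevelopmental disorders	
BD21	Nonorganic psychosis	F29	Schizophrenia Spectrum Disorder and other psychotic disorders	
BD22	Obsessive-Compulsive Disorder	F42;F42.9;F42.8	Obsessive-compulsive and related disorders	
BD23	Paranoia	F22	Schizophrenia Spectrum Disorder and other psychotic disorders	
BD24	Profound Intellectual Disability	F73	Neurodevelopmental disorders	
BD25	Psychosis, Brief Reactive	F23	Schizophrenia Spectrum Disorder and other psychotic disorders	
BD26	Schizoaffective disorder, bipolar type	F25.0	Schizophrenia Spectrum Disorder and other psychotic disorders	
BD27	Schizophreniform Disorders	F20.81	Schizophrenia Spectrum Disorder and other psychotic disorders	schizophreniform
BD28	Schizophreniform psychosis NOS	F20.81	Schizophrenia Spectrum Disorder and other psychotic disorders	schizophreniform
BD29	Schizotypal Personality Disorder	F21	Schizophrenia Spectrum Disorder and other psychotic disorders/Personality Disorders	
BD30	Severe Intellectual Disability	F72	Neurodevelopmental disorders	
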