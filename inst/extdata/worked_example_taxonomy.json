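{"code_base":10,"symptom_names":["gender","fever","ulcer","pain","aching_and_limp","nasal_congestion","diarrhea","bleeding","tumor","drowsiness","face_yellowing"],"categories":[{"b":1,"name":"tumor_disease","subclasses":[{"j":1,"name":"benign_tumor","diseases":[{"t":1,"name":"squamous_cell_carcinoma"},{"t":2,"name":"adenocarcinoma"},{"t":3,"name":"basal_cell_carcinoma"},{"t":4,"name":"transitional_cell_carcinoma"},{"t":5,"name":"sarcoma"}]},{"j":2,"name":"borderline_tumor","diseases":[]},{"j":3,"name":"malignant_tumor","diseases":[]}]},{"b":2,"name":"infectious_disease","subclasses":[]},{"b":3,"name":"blood_disease","subclasses":[]},{"b":4,"name":"cardiovascular_disease","subclasses":[]},{"b":5,"name":"digestive_disease","subclasses":[]},{"b":6,"name":"endocrine_system_disease","subclasses":[]},{"b":7,"name":"respiratory_disease","subclasses":[]},{"b":8,"name":"urinary_system_disease","subclasses":[]},{"b":9,"name":"ophthalmic_disease","subclasses":[]},{"b":10,"name":"otolaryngology_disease","subclasses":[]}]}
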