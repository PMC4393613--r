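<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">

  <!-- Interchange format for phenotyping schemes: self-contained documents
       carrying term labels, ontology CURIEs, units, categorical domains and
       value image references, so capture devices need no registry access. -->

  <xs:simpleType name="curie">
    <xs:restriction base="xs:string">
      <xs:pattern value="[A-Za-z][A-Za-z0-9]*:[0-9]+"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="datatype">
    <xs:restriction base="xs:string">
      <xs:enumeration value="numeric"/>
      <xs:enumeration value="categorical"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="nonempty">
    <xs:restriction base="xs:string">
      <xs:minLength value="1"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:element name="phenotyping_scheme">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="entity" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="label" type="nonempty"/>
              <xs:element name="parameter" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="label" type="nonempty"/>
                    <xs:element name="value" minOccurs="0" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:sequence>
                          <xs:element name="label" type="nonempty"/>
                        </xs:sequence>
                        <xs:attribute name="id" type="nonempty" use="required"/>
                        <xs:attribute name="image" type="xs:string"/>
                        <xs:attribute name="image_checksum" type="xs:string"/>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                  <xs:attribute name="id" type="nonempty" use="required"/>
                  <xs:attribute name="ontology_ref" type="curie"/>
                  <xs:attribute name="datatype" type="datatype" use="required"/>
                  <xs:attribute name="unit" type="xs:string"/>
                  <xs:attribute name="required" type="xs:boolean" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="id" type="nonempty" use="required"/>
            <xs:attribute name="ontology_ref" type="curie"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="id" type="nonempty" use="required"/>
      <xs:attribute name="name" type="nonempty" use="required"/>
      <xs:attribute name="owner" type="nonempty" use="required"/>
      <xs:attribute name="language" type="nonempty" use="required"/>
      <xs:attribute name="created" type="nonempty" use="required"/>
    </xs:complexType>
  </xs:element>

</xs:schema>
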